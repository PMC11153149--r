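# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

## Lower-middle median: for an odd number of values this is the ordinary
## sample median; for an even number the lower of the two middle values is
## returned, which keeps integer counts integral and is the conservative
## choice for a background-rate estimate.
lower_median <- function(x) {
  m <- length(x)
  if (m == 0L) stopf("lower_median(): empty input")
  k <- (m + 1L) %/% 2L
  sort.int(x, partial = k)[k]
}

## Standard error of the mean across biological repeats (sample sd / sqrt(n));
## defined as 0 for a single repeat.
sem <- function(x) {
  n <- length(x)
  if (n <= 1L) return(0)
  stats::sd(x) / sqrt(n)
}

## Reverse complement of a plain character string (A/C/G/T/N alphabet).
revcomp <- function(x) {
  vapply(x, function(s) {
    ch <- rev(strsplit(chartr("ACGTNacgtn", "TGCANTGCAN", s), "", fixed = TRUE)[[1L]])
    paste0(ch, collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

check_orientation <- function(x, what = "orientation") {
  if (!all(x %in% c("+", "-"))) {
    stopf("%s must be '+' or '-'", what)
  }
  invisible(x)
}

## Extract one chromosome as a character vector of single bases.
chrom_chars <- function(genome, chrom) {
  strsplit(as.character(get_chrom_seq(genome, chrom)), "", fixed = TRUE)[[1L]]
}

get_chrom_seq <- function(genome, chrom) {
  if (!chrom %in% names(genome)) stopf("unknown chromosome '%s'", chrom)
  genome[[chrom]]
}

## Merge 0-based half-open intervals; only *overlapping* intervals are merged
## (adjacent intervals stay separate).  Returns a data.frame with a `members`
## list column of input row indices.
merge_intervals <- function(start, end) {
  n <- length(start)
  if (n == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  o <- order(start, end)
  ms <- me <- integer(0)
  members <- list()
  cur_s <- start[o[1L]]; cur_e <- end[o[1L]]; cur_m <- o[1L]
  for (i in o[-1L]) {
    if (start[i] < cur_e) {
      cur_e <- max(cur_e, end[i])
      cur_m <- c(cur_m, i)
    } else {
      ms <- c(ms, cur_s); me <- c(me, cur_e); members[[length(members) + 1L]] <- cur_m
      cur_s <- start[i]; cur_e <- end[i]; cur_m <- i
    }
  }
  ms <- c(ms, cur_s); me <- c(me, cur_e); members[[length(members) + 1L]] <- cur_m
  out <- data.frame(start = ms, end = me)
  out$members <- members
  out
}
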