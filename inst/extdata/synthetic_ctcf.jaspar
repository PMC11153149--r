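>SYN0001.1 synthetic_CTCF_like
A  [    1    1  997    1    1  997    1    1    1    1    1    1  997    1    1    1    1    1    1 ]
C  [  997  997    1    1  997    1    1    1    1    1    1  997    1    1  997    1    1    1    1 ]
G  [    1    1    1  997    1    1  997  997  997  997  997    1    1  997    1    1  997    1    1 ]
T  [    1    1    1    1    1    1    1    1    1    1    1    1    1    1    1  997    1  997  997 ]
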