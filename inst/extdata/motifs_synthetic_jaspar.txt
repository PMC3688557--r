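>SYN_NRHALF synthetic
A [ 18 0 1 0 2 18 18 0 1 1 2 18 ]
C [ 0 0 0 1 18 1 2 2 1 2 18 2 ]
G [ 1 18 18 2 1 1 1 18 18 0 0 0 ]
T [ 1 1 1 18 0 1 0 1 0 18 1 0 ]
>SYN_FOXA synthetic
A [ 2 2 0 2 2 18 2 0 0 18 ]
C [ 1 0 2 0 2 0 18 2 0 1 ]
G [ 1 18 2 0 2 1 2 1 0 1 ]
T [ 18 2 18 18 18 1 2 18 18 2 ]
>SYN_TATA synthetic
A [ 1 1 18 2 18 18 18 18 1 0 ]
C [ 18 1 0 1 2 0 1 0 1 2 ]
G [ 2 0 0 0 1 0 2 2 18 18 ]
T [ 1 18 0 18 1 1 1 1 0 2 ]
>SYN_CEBP synthetic
A [ 18 0 0 0 2 1 1 18 18 0 ]
C [ 0 0 1 2 18 2 18 1 2 0 ]
G [ 1 2 0 18 1 18 2 1 2 1 ]
T [ 1 18 18 1 1 2 1 0 2 18 ]
>SYN_TCF synthetic
A [ 18 2 2 1 0 2 1 1 0 2 ]
C [ 0 18 0 2 0 0 0 1 18 2 ]
G [ 0 2 1 1 2 18 0 0 1 1 ]
T [ 1 2 18 18 18 2 18 18 0 18 ]
>SYN_ZNF synthetic
A [ 2 1 0 18 2 0 2 1 0 1 ]
C [ 0 2 1 0 1 1 2 1 18 18 ]
G [ 18 18 18 1 18 18 18 18 2 0 ]
T [ 1 0 1 1 2 1 1 0 2 2 ]
>DECOY01 synthetic
A [ 18 18 18 2 18 2 1 1 0 1 ]
C [ 0 2 0 18 0 0 2 0 18 1 ]
G [ 1 0 1 1 0 1 0 2 2 18 ]
T [ 0 2 2 2 1 18 18 18 1 0 ]
>DECOY02 synthetic
A [ 0 0 1 2 18 18 0 0 2 2 ]
C [ 18 1 2 2 1 0 0 2 0 2 ]
G [ 2 1 2 18 1 0 18 1 18 2 ]
T [ 1 18 18 1 2 2 0 18 1 18 ]
>DECOY03 synthetic
A [ 1 0 0 18 1 0 18 0 18 0 ]
C [ 0 0 2 2 1 18 2 1 0 0 ]
G [ 18 18 18 1 18 1 0 18 0 2 ]
T [ 1 2 0 0 1 1 2 0 2 18 ]
>DECOY04 synthetic
A [ 2 0 0 0 2 1 18 0 0 0 ]
C [ 1 2 2 2 1 1 1 18 18 2 ]
G [ 0 18 0 18 0 18 2 1 1 1 ]
T [ 18 0 18 2 18 2 2 1 2 18 ]
>DECOY05 synthetic
A [ 18 1 2 2 18 0 1 18 0 2 ]
C [ 2 2 0 0 0 0 1 2 1 2 ]
G [ 0 18 18 0 2 1 0 2 18 18 ]
T [ 2 1 0 18 1 18 18 2 1 0 ]
>DECOY06 synthetic
A [ 0 1 2 1 18 18 0 1 0 0 ]
C [ 0 18 0 18 2 2 1 0 18 1 ]
G [ 18 2 1 2 0 1 18 2 2 18 ]
T [ 0 2 18 0 0 1 0 18 2 0 ]
>DECOY07 synthetic
A [ 2 1 2 18 18 2 1 2 2 1 ]
C [ 1 0 18 1 2 1 18 0 18 0 ]
G [ 18 2 1 2 2 2 0 0 2 2 ]
T [ 1 18 1 1 2 18 0 18 1 18 ]
>DECOY08 synthetic
A [ 1 0 0 2 1 1 2 2 18 1 ]
C [ 0 2 18 1 2 2 1 2 2 18 ]
G [ 18 18 1 18 18 18 1 18 1 2 ]
T [ 1 2 2 2 2 0 18 0 1 2 ]
>DECOY09 synthetic
A [ 1 2 2 18 18 0 0 2 1 18 ]
C [ 0 18 2 2 0 0 18 0 18 1 ]
G [ 18 0 2 1 2 18 1 18 1 2 ]
T [ 2 0 18 1 2 0 2 2 1 2 ]
>DECOY10 synthetic
A [ 1 0 0 1 0 2 0 2 0 0 ]
C [ 18 2 1 1 2 2 18 0 18 1 ]
G [ 0 18 18 2 18 18 2 2 1 0 ]
T [ 0 0 1 18 0 0 2 18 0 18 ]
>DECOY11 synthetic
A [ 2 1 18 2 18 0 0 1 2 1 ]
C [ 2 18 2 0 1 18 18 18 2 2 ]
G [ 1 0 1 18 0 2 1 0 18 18 ]
T [ 18 0 2 2 0 2 0 2 2 0 ]
>DECOY12 synthetic
A [ 2 2 2 0 18 1 0 18 18 18 ]
C [ 0 1 18 18 1 0 0 2 0 0 ]
G [ 18 18 1 0 2 0 0 1 1 1 ]
T [ 1 2 1 1 1 18 18 2 1 0 ]
>DECOY13 synthetic
A [ 18 18 0 0 18 18 1 0 18 0 ]
C [ 0 1 18 2 2 1 1 2 1 0 ]
G [ 0 0 2 18 0 1 1 18 2 1 ]
T [ 1 0 0 2 2 2 18 1 0 18 ]
>DECOY14 synthetic
A [ 1 2 1 0 18 0 0 2 18 18 ]
C [ 1 2 18 18 1 18 0 0 1 0 ]
G [ 18 18 0 1 0 0 2 1 2 0 ]
T [ 2 2 1 1 1 1 18 18 0 2 ]
>DECOY15 synthetic
A [ 0 18 18 0 0 2 18 2 18 0 ]
C [ 18 0 1 18 1 18 2 18 1 18 ]
G [ 1 1 1 0 18 1 0 0 2 1 ]
T [ 2 0 1 0 1 1 1 1 2 1 ]
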