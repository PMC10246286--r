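# Synthetic stand-in for an ion-channel gene list (GO:0005216-style);
# the real annotation set is user-supplied. One gene per line.
KCNA1
KCNB1
KCNC1
KCND2
KCNJ3
KCNJ6
KCNMA1
KCNN1
KCNQ2
KCNQ3
SCN1A
SCN2A
SCN8A
CACNA1A
CACNA1B
CACNA1C
CACNA1G
CACNG2
GRIN1
GRIN2A
GRIA1
GRIK1
GABRA1
GABRB2
HCN1
HCN2
TRPC3
TRPM4
RYR2
ITPR1
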