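# synthetic example morphology: soma, stem, Y-fork (um)
1 1 50 50 20 5 -1
2 3 52 50 22 0.5 1
3 3 55 51 25 0.5 2
4 3 58 52 28 0.5 3
5 3 60 55 31 0.5 4
6 3 62 58 35 0.5 5
7 3 60 50 30 0.5 4
8 3 62 49 32 0.5 7
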