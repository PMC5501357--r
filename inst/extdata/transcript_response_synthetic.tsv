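accession	max_abs_fold
P05362	12.5
Q07325	54.0
Q10589	8.2
P04233	3.1
Q03518	22.4
P19320	6.8
P13747	4.4
Q9NZQ7	30.0
P61769	5.9
P25774	2.0
O95864	1.9
Q16647	1.4
P02671	2.6
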