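step	value
AA	8.9
AC	9.6
AG	8.4
AT	13.6
CA	12.2
CC	6.9
CG	11.0
GA	9.1
GC	8.6
TA	16.4
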