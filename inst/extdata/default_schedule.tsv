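# Pre-MBT cycle schedule, reconstructed to match the printed anchors:
# cycle-8 transcriptional window ~12 s (interphase 4.2 min with a 4-min lag),
# S phase 7 min at cycle 10 and 15 min at cycle 13, mitosis ~5 min.
# Cycles 9, 11, 12 are monotone interpolations; cycle 14 is terminal
# (unbounded interphase; the tabulated value is nominal).
cycle	interphase_min	mitosis_min
8	4.2	5
9	5.5	5
10	7	5
11	9.5	5
12	12	5
13	15	5
14	70	5
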