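column
8
9
11
12
13
14
16
17
19
20
21
26
27
28
29
31
33
36
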