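>ELT1_N synthetic class template: amino DBD of tandem-finger factors (TPLWRR)
CVNCGATATPLWRRDGTGHYLCNACGLYHKMNGQNRPLIRPKKRNSNKSKKSKRH
>ELT1_C synthetic class template: carboxyl DBD of tandem-finger factors (TTLWRR)
CANCQTTTTLWRRNASGDPVACNACGLYYKLHQVNRPLTMRKDGIQTRNRKVSSR
>ELT2 synthetic class template: single DBD downstream of a degenerate C4 finger (TTLWRR)
CSNCHTTTLWRRTPEGGHVSLCGTCKANRRQGLSYHRKMNKFNRPMMKKEGIQTR
>ELT3 synthetic class template: single short-tailed DBD (TSLWRR)
CTTCGVTSLWRRNNEGEPVLMCQSCTTNRRVGISGRKDAHNFQLPVVKPQSHSRN
>ELT5 synthetic class template: single DBD with long tail (TTAWRR)
CKECWNTTAWRRAMSPDKSLVCIYCHKMNGENRPLIKPKRRLSVAQRRAGLQTGK
>ELTX synthetic class template: diverged single DBD (no diagnostic hexapeptide)
CPGCADNFGHQYMEPSVIGNTCMDCNQAYKDGSFMRPHVETNAGDYFQLRSPIVH
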