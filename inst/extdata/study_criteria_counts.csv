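profile,tp,fp,fn,sensitivity_published,precision_published,miss_rate_published,fdr_published
loosened,24,42,9,72.7,NA,NA,63.7
proposed,17,28,10,62.96,37.78,37.04,62.22
stricter,9,13,15,37.5,NA,NA,59.1
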