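# shared environment so the melt recovery study is computed once and
# reused by both the Tm and the enthalpy checks
.acceptance_cache <- new.env(parent = emptyenv())
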