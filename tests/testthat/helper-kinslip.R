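# Shared objects for the suite.
kip3 <- motor_preset("kip3_table1")
cond_sat0 <- motor_condition(0, "saturating")

# Delta-method standard error of an empirical forward/backward count ratio.
ratio_se <- function(r, n_fwd, n_bwd) r * sqrt(1 / n_fwd + 1 / n_bwd)
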