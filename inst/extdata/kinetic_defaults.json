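{
  "_comment": "Default kinetic parameters of the Monte-Carlo transcription model. Rates never published for this system ship as documented defaults; retention_mean 50 s is the fast regime (660 s = 11 min is the slow regime) and splice_depletion_bp 750 is the basal splicing-efficiency distance (500 under Clk1 overexpression).",
  "init_rate": 0.05,
  "elong_rate": 55,
  "pause_on_rate": 0.01,
  "pause_off_rate": 0.1,
  "termination_rate": 0.2,
  "retention_mean": 50,
  "retention_model": "fixed",
  "splice_depletion_bp": 750,
  "dt": 0.1
}
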