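trial_id,arm,n,responders
Trial 1,Anchor,200,94
Trial 1,Reference,200,85
Trial 2,Anchor,350,183
Trial 2,Placebo,350,64
Trial 3,Anchor,100,53
Trial 3,Placebo,50,5
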