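"category","pattern"
"health","sick"
"health","pain"
"health","hosp*"
"informal","lol"
"informal","u"
"informal",":)"
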