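"word","weight"
"sick",2
"happy",-1
"lol",0.5
"(intercept)",0.1
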