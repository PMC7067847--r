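"topic_id","word","weight"
"t1","hospital",0.9
"t1","pain",0.6
"t2","pain",0.2
"t2","happy",0.5
"t2","lol",1
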