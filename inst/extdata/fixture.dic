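%
1	affect
2	body
%
happy	1
sad	1
glad	1
arm	2
leg	2
head	2
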