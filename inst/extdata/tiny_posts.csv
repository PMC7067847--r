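"patient_id","timestamp","text"
"p1","2014-05-31T09:17:00","feel better today"
"p1","2014-06-05T12:34:00","so so so happy"
"p1","2014-06-10T15:51:00","sick sick pain hospital today"
"p1","2014-05-16T18:08:00","the pain is better today"
"p1","2014-04-19T10:17:00","u lol :) :)"
"p1","2014-04-24T13:34:00","the and so i'm"
"p1","2014-04-29T16:51:00","i'm so tired and sick"
"p1","2014-04-04T19:08:00","happy happy :) u"
"p1","2014-03-06T11:17:00","hospital pain sick"
"p1","2014-03-11T14:34:00","lol u :) happy"
"p1","2014-02-14T17:51:00","hospitals are the worst lol"
"p1","2014-02-19T20:08:00","pain pain sick lol"
"p1","2014-01-22T12:17:00","sick sick pain hospital today"
"p1","2014-01-27T15:34:00","the pain is better today"
"p1","2014-01-02T18:51:00","feel better today"
"p1","2014-01-07T21:08:00","so so so happy"
"p2","2014-06-07T14:17:00","pain pain sick lol"
"p2","2014-06-12T17:34:00","hospital pain sick"
"p2","2014-05-18T20:51:00","lol u :) happy"
"p2","2014-04-26T15:17:00","so so so happy"
"p2","2014-04-01T18:34:00","sick sick pain hospital today"
"p2","2014-04-06T21:51:00","the pain is better today"
"p2","2014-03-13T16:17:00","the and so i'm"
"p2","2014-02-16T19:34:00","i'm so tired and sick"
"p2","2014-02-21T22:51:00","happy happy :) u"
"p2","2013-12-30T17:17:00","lol u :) happy"
"p2","2014-01-04T20:34:00","hospitals are the worst lol"
"p2","2014-01-09T23:51:00","pain pain sick lol"
"p3","2014-06-14T19:17:00","u lol :) :)"
"p3","2014-05-20T22:34:00","the and so i'm"
"p3","2014-05-25T01:51:00","i'm so tired and sick"
"p3","2014-04-03T20:17:00","hospital pain sick"
"p3","2014-04-08T23:34:00","lol u :) happy"
"p3","2014-04-13T02:51:00","hospitals are the worst lol"
"p3","2014-02-18T21:17:00","sick sick pain hospital today"
"p3","2014-02-23T00:34:00","the pain is better today"
"p3","2014-02-28T03:51:00","feel better today"
"p3","2014-01-06T22:17:00","i'm so tired and sick"
"p3","2014-01-11T01:34:00","happy happy :) u"
"p3","2014-01-16T04:51:00","u lol :) :)"
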