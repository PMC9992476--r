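{"id":"p01","channel":"blog","date":"2020-01-02","text":"big giveaway today get your Ketotop sample now http://shop.example.com/deal"}
{"id":"p02","channel":"blog","date":"2020-01-03","text":"limited coupon for pain patches visit our store"}
{"id":"p03","channel":"cafe","date":"2020-01-05","text":"Ketotop Gel helped but I got a rash on my arm"}
{"id":"p04","channel":"blog","date":"2020-01-06","text":"used Fastum Gel after the gym and felt dizziness all evening"}
{"id":"p05","channel":"cafe","date":"2020-01-07","text":"ketoprofen patch caused itching for two days"}
{"id":"p06","channel":"blog","date":"2020-02-01","text":"ketoprofen patch caused itching for two days"}
{"id":"p07","channel":"cafe","date":"2020-01-09","text":"applied Antiphlamine before the marathon no problems at all"}
{"id":"p08","channel":"blog","date":"2020-01-10","text":"my knee has been sore since the hike last weekend"}
{"id":"p09","channel":"cafe","date":"2020-01-11","text":"went hiking yesterday the weather was lovely"}
{"id":"p10","channel":"blog","date":"2020-01-12","text":"grandma recommends some ointment for sore joints"}
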