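ingredient	surface_term
Ketoprofen	Ketoprofen
Ketoprofen	Rheutin Cap
Ketoprofen	Cyprogel Ointment 3%
Ketoprofen	Ketotop
Ketoprofen	Kenofen Gel
Ketoprofen	Kefentech Plaster
Ketoprofen	Ketotop Gel
Ketoprofen	Fastum Gel
Ketoprofen	Antiphlamine
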