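soc,count
Skin and appendages disorders,412
Body as a whole - general disorders,186
Central and peripheral nervous system disorders,120
Gastro-intestinal system disorders,95
Musculo-skeletal system disorders,61
Psychiatric disorders,24
Respiratory system disorders,11
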