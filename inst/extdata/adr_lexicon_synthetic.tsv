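surface_term	preferred_term	soc	source
rash	Rash	Skin and appendages disorders	terminology_a
rashes	Rash	Skin and appendages disorders	terminology_b
itching	Pruritus	Skin and appendages disorders	terminology_a
itchy	Pruritus	Skin and appendages disorders	consumer
dry	Skin dry	Skin and appendages disorders	terminology_b
flushing	Flushing	Skin and appendages disorders	terminology_a
dizziness	Dizziness	Central and peripheral nervous system disorders	terminology_a
headache	Headache	Central and peripheral nervous system disorders	terminology_b
spasm	Muscle spasms	Musculo-skeletal system disorders	terminology_a
muscle pain	Myalgia	Musculo-skeletal system disorders	terminology_b
swelling	Oedema	Body as a whole - general disorders	terminology_a
edema	Oedema	Body as a whole - general disorders	terminology_b
nausea	Nausea	Gastro-intestinal system disorders	terminology_a
vomiting	Vomiting	Gastro-intestinal system disorders	terminology_a
anxiety	Anxiety	Psychiatric disorders	terminology_b
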