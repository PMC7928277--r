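prescription_id,pharmacy_id,raw_material_name
P1,PH01,Tang kuei
P1,PH01,T'ung ts'ao
P1,PH01,Hung ch'i
P2,PH01,"Angelica sinensis (Oliv.) Diels"
P2,PH01,"  tang  kuei "
P2,PH01,T'ung ts'ao
P3,PH02,Tang kuei
P3,PH02,Kou ch'i
P3,PH02,Kan ts'ao
P4,PH03,T'ung ts'ao
P4,PH03,Hung ch'i
P5,PH03,Tang kuei
P5,PH03,T'ung ts'ao
P5,PH03,Kan ts'ao
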