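clinical,PRL,TSH,GH,ACTH,LH,FSH,PIT1,SF1,TPIT,who2022_type
Non-functioning,−,−,−,−,−,−,−,−,−,Null cell tumour
Non-functioning,−,−,−,−,−,−,−,+,+,Plurihormonal tumour
Non-functioning,+,+,+,−,−,−,−,−,−,Plurihormonal tumour
Non-functioning,−,−,−,−,−,+,+,+,−,Plurihormonal tumour
Non-functioning,+,−,−,−,−,−,+,+,−,Plurihormonal tumour
Non-functioning,−,−,−,−,−,+,−,+,+,Plurihormonal tumour
Acromegaly,+,+,+,−,−,−,+,+,−,Plurihormonal tumour
Acromegaly,+,+,+,−,−,−,+,+,−,Plurihormonal tumour
Acromegaly,−,−,+,−,−,+,+,+,+,Plurihormonal tumour
Acromegaly,−,+,+,−,−,−,+,+,−,Plurihormonal tumour
Acromegaly,+,+,+,−,−,−,+,+,−,Plurihormonal tumour
Prolactinoma,+,−,−,−,−,−,+,+,−,Plurihormonal tumour
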