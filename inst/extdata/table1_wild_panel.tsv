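sample_id	sex	country	location
Sa283g	male	Belgium	NA
Sa668a	male	Sweden	Oland
Sa984	male	England	NA
Sa526b	female	Austria	Stift Melk
Sa615	female	Germany	NA
Sa758d	female	Russian Federation	Moscow
Sa833d	female	Spain	NA
Sa985	female	Austria	NA
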