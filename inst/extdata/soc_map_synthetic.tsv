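Abortion	Pregnancy, Puerperium and Perinatal Conditions
Foetal death	Pregnancy, Puerperium and Perinatal Conditions
Premature delivery	Pregnancy, Puerperium and Perinatal Conditions
Premature labor	Pregnancy, Puerperium and Perinatal Conditions
Maternal drugs affecting foetus	Injury, Poisoning and Procedural Complications
Maternal exposure during pregnancy	Injury, Poisoning and Procedural Complications
Maternal exposure timing unspecified	Injury, Poisoning and Procedural Complications
Foetal exposure during pregnancy	Injury, Poisoning and Procedural Complications
Death neonatal	General disorders and administration site conditions
Adverse event	General disorders and administration site conditions
Drug ineffective	General disorders and administration site conditions
Fatigue	General disorders and administration site conditions
Pyrexia	General disorders and administration site conditions
Nausea	Gastrointestinal disorders
Vomiting	Gastrointestinal disorders
Diarrhoea	Gastrointestinal disorders
Headache	Nervous system disorders
Dizziness	Nervous system disorders
Rash	Skin and subcutaneous tissue disorders
Pruritus	Skin and subcutaneous tissue disorders
Dyspnoea	Respiratory, thoracic and mediastinal disorders
Cough	Respiratory, thoracic and mediastinal disorders
Alanine aminotransferase increased	Investigations
Renal impairment	Renal and urinary disorders
Bradycardia	Cardiac disorders
Hepatotoxicity	Hepatobiliary disorders
Anaemia	Blood and lymphatic system disorders
Insomnia	Psychiatric disorders
Hypotension	Vascular disorders
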