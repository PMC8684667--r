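code,name,category
C,Clinical activity,
C.E,Evaluation,Evaluation
C.E.1,Neurological evaluation,
C.E.1.1,NIHSS assessment,
C.E.1.2,Glasgow coma scale,
C.E.2,General evaluation,
C.E.2.1,Consciousness evaluation,
C.E.2.2,Swallowing function evaluation,
C.O,Observation,Observation
C.O.1,Electrophysiological examination,
C.O.1.1,ECG,
C.O.1.2,EEG,
C.O.2,Imaging examination,
C.O.2.1,Head CT,
C.O.2.2,Head MRI,
C.O.2.3,TCCD,
C.O.2.4,Chest X-ray,
C.O.3,Laboratory test,
C.O.3.1,Blood routine test,
C.O.3.2,Coagulation function test,
C.O.3.3,Blood glucose test,
C.O.3.4,Detection of myocardial ischemia markers,
C.O.3.5,B-type natriuretic peptide,
C.O.3.6,Renal function test,
C.D,Drug,Drug
C.D.1,Antimicrobial drugs,
C.D.1.1,Antibacterial drugs,
C.D.1.1.1,Penicillins,
C.D.1.1.1.1,Benzylpenicillin,
C.D.1.1.1.2,Amoxicillin,
C.D.2,Cardiovascular drugs,
C.D.2.1,Antihypertensive drugs,
C.D.2.1.1,Nitrendipine,
C.D.2.1.2,Nifedipine,
C.D.3,Thrombolytic drugs,
C.D.3.1,rt-PA,
C.D.3.2,Urokinase,
C.D.4,Neuroprotective drugs,
C.D.4.1,Edaravone,
C.D.4.2,Chinese traditional patent medicine,
C.D.5,Anti-dementia drugs,
C.D.5.1,Olacetam,
C.P,Operation,Operation
C.P.1,Nursing,
C.P.1.1,Blood pressure measurement,
C.P.1.2,Venous catheterization,
C.P.1.3,Oxygen inhalation,
C.P.2,Treatment,
C.P.2.1,Intravenous infusion,
C.A,Artificial,Artificial
C.A.1,Onset,
C.A.2,Arrive at hospital,
C.A.3,Arrive at neurology department,
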