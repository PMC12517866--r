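name	atc_code
ATORVASTATIN	C10AA05
ATORVASTATIN CALCIUM	C10AA05
LIPITOR	C10AA05
ROSUVASTATIN	C10AA07
ROSUVASTATIN CALCIUM	C10AA07
CRESTOR	C10AA07
SIMVASTATIN	C10AA01
ZOCOR	C10AA01
PRAVASTATIN	C10AA03
LOVASTATIN	C10AA02
FLUVASTATIN	C10AA04
PITAVASTATIN	C10AA08
IBUPROFEN	M01AE01
METFORMIN	A10BA02
METFORMIN HYDROCHLORIDE	A10BA02
ASPIRIN	B01AC06
LISINOPRIL	C09AA03
AMLODIPINE	C08CA01
OMEPRAZOLE	A02BC01
LEVOTHYROXINE	H03AA01
LEVOTHYROXINE SODIUM	H03AA01
GABAPENTIN	N03AX12
SERTRALINE	N06AB06
ALBUTEROL	R03AC02
SALBUTAMOL	R03AC02
PREDNISONE	H02AB07
WARFARIN	B01AA03
CLOPIDOGREL	B01AC04
FUROSEMIDE	C03CA01
METOPROLOL	C07AB02
LOSARTAN	C09CA01
PANTOPRAZOLE	A02BC02
ESOMEPRAZOLE	A02BC05
HYDROCHLOROTHIAZIDE	C03AA03
INSULIN GLARGINE	A10AE04
ACETAMINOPHEN	N02BE01
PARACETAMOL	N02BE01
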