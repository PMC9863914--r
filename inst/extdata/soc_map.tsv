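pt	soc_code
Atrial fibrillation	10007541
Atrial flutter	10007541
Supraventricular tachycardia	10007541
Supraventricular arrhythmia	10007541
Ventricular tachycardia	10007541
Ventricular fibrillation	10007541
Cardiac arrest	10007541
Cardiac failure	10007541
Cardiac failure congestive	10007541
Cardiomyopathy	10007541
Cardiomegaly	10007541
Atrioventricular block	10007541
Bundle branch block left	10007541
Myocardial infarction	10007541
Acute coronary syndrome	10007541
Torsade de pointes	10007541
Sinus node dysfunction	10007541
Sinus bradycardia	10007541
Sinus arrest	10007541
Cerebral haemorrhage	10029205
Haemorrhage intracranial	10029205
Subdural haematoma	10029205
Cerebral infarction	10029205
Cerebrovascular accident	10029205
Transient ischaemic attack	10029205
Cerebral haematoma	10029205
Hemiplegia	10029205
Hypertension	10047065
Hypertensive crisis	10047065
Pulmonary hypertension	10047065
Pulmonary arterial hypertension	10047065
Deep vein thrombosis	10047065
Pulmonary embolism	10047065
Embolism arterial	10047065
Peripheral artery thrombosis	10047065
Thrombosis	10047065
Embolism	10047065
Electrocardiogram QT prolonged	10022891
Ejection fraction decreased	10022891
Blood pressure increased	10022891
Haemorrhage	10005329
Fatigue	10018065
Nausea	10017947
Headache	10029205
Diarrhoea	10017947
Pyrexia	10018065
Rash	10040785
Dizziness	10029205
Vomiting	10017947
Arthralgia	10028395
Cough	10038738
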