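pt	smq_name	smq_code	scope
Atrial fibrillation	Supraventricular tachyarrhythmias	20000057	narrow
Atrial flutter	Supraventricular tachyarrhythmias	20000057	narrow
Supraventricular tachycardia	Supraventricular tachyarrhythmias	20000057	narrow
Supraventricular arrhythmia	Supraventricular tachyarrhythmias	20000057	broad
Cerebral haemorrhage	Haemorrhagic central nervous system vascular conditions	20000064	narrow
Haemorrhage intracranial	Haemorrhagic central nervous system vascular conditions	20000064	narrow
Subdural haematoma	Haemorrhagic central nervous system vascular conditions	20000064	narrow
Ventricular tachycardia	Ventricular tachyarrhythmias	20000058	narrow
Ventricular fibrillation	Ventricular tachyarrhythmias	20000058	narrow
Cardiac arrest	Ventricular tachyarrhythmias	20000058	broad
Cardiac failure	Cardiac failure	20000004	narrow
Cardiac failure congestive	Cardiac failure	20000004	narrow
Ejection fraction decreased	Cardiac failure	20000004	broad
Cerebral infarction	Ischaemic central nervous system vascular conditions	20000063	narrow
Cerebrovascular accident	Ischaemic central nervous system vascular conditions	20000063	narrow
Transient ischaemic attack	Ischaemic central nervous system vascular conditions	20000063	narrow
Sinus node dysfunction	Disorders of sinus node function	20000055	narrow
Sinus bradycardia	Disorders of sinus node function	20000055	narrow
Sinus arrest	Disorders of sinus node function	20000055	narrow
Cardiomyopathy	Cardiomyopathy	20000150	narrow
Cardiomegaly	Cardiomyopathy	20000150	broad
Atrioventricular block	Conduction defects	20000056	narrow
Bundle branch block left	Conduction defects	20000056	narrow
Myocardial infarction	Myocardial infarction	20000047	narrow
Acute coronary syndrome	Myocardial infarction	20000047	narrow
Torsade de pointes	Torsade de pointes/QT prolongation	20000001	narrow
Electrocardiogram QT prolonged	Torsade de pointes/QT prolongation	20000001	narrow
Ventricular fibrillation	Torsade de pointes/QT prolongation	20000001	broad
Embolism arterial	Embolic and thrombotic events, arterial	20000082	narrow
Peripheral artery thrombosis	Embolic and thrombotic events, arterial	20000082	narrow
Deep vein thrombosis	Embolic and thrombotic events, venous	20000083	narrow
Pulmonary embolism	Embolic and thrombotic events, venous	20000083	narrow
Hypertension	Hypertension	20000147	narrow
Blood pressure increased	Hypertension	20000147	broad
Hypertensive crisis	Hypertension	20000147	narrow
Cerebral haematoma	Conditions associated with central nervous system haemorrhages and cerebrovascular accidents	20000166	narrow
Hemiplegia	Conditions associated with central nervous system haemorrhages and cerebrovascular accidents	20000166	broad
Pulmonary hypertension	Pulmonary hypertension	20000130	narrow
Pulmonary arterial hypertension	Pulmonary hypertension	20000130	narrow
Thrombosis	Embolic and thrombotic events, vessel type unspecified and mixed arterial and venous	20000168	narrow
Embolism	Embolic and thrombotic events, vessel type unspecified and mixed arterial and venous	20000168	narrow
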