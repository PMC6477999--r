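code	label	category
macrocephaly	Macrocephaly	craniofacial
tall_prominent_forehead	Tall and prominent forehead	craniofacial
coarse_face	Coarse face	craniofacial
elongated_face	Elongated face	craniofacial
widely_spaced_eyes	Widely spaced eyes	craniofacial
epicanthic_folds	Epicanthic folds	craniofacial
ptosis	Ptosis	craniofacial
low_set_ears	Low-set ears	craniofacial
depressed_nasal_root	Short, broad, depressed nasal root	craniofacial
prominent_nasolabial_folds	Prominent naso-labial folds	craniofacial
high_wide_vermilion	High wide peaks of the vermilion	craniofacial
short_neck	Short neck	neck_thorax
webbed_neck	Webbed neck	neck_thorax
pectus_deformity	Pectus deformity of the chest	neck_thorax
broad_thorax	Broad thorax	neck_thorax
short_stature	Short stature	growth
height_below_p10	Height below 10th centile	growth
typical_facial_features	Typical facial features	facies
suggestive_facial_features	Suggestive (mild) facial features	facies
pulmonary_valve_stenosis	Pulmonary valve stenosis	cardiovascular
hypertrophic_cardiomyopathy	Hypertrophic cardiomyopathy	cardiovascular
left_axis_deviation	Left axis deviation on ECG	cardiovascular
aortic_valve_stenosis	Aortic valve stenosis	cardiovascular
mitral_valve_incompetence	Mitral valve incompetence	cardiovascular
coarctation_of_aorta	Coarctation of the aorta	cardiovascular
bicuspid_aortic_valve	Bicuspid aortic valve	cardiovascular
septal_defect	Septal defect	cardiovascular
walked_by_18_months	Walked before 18 months	development
unable_to_walk_after_24_months	Unable to walk after 24 months	development
speech_delay	Speech delay	development
motor_delay	Motor delay	development
mild_intellectual_disability	Mild intellectual disability	development
mild_developmental_delay	Mild developmental delay	development
learning_difficulties	Learning difficulties	development
family_history_definite_ns	First-degree relative with definite NS	family
family_history_suggestive_ns	First-degree relative with suggestive NS	family
cryptorchidism	Cryptorchidism / undescended testis	other
lymphatic_dysplasia	Lymphatic dysplasia	other
strabismus	Strabismus	eye
curly_hair	Curly hair	dermatologic
bleeding_diathesis	Bleeding diathesis	hematologic
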