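# Grouping of the 30 raw KHPS chronic-condition codes into 14 disease
# categories. Editable: each key is a grouped category, each list entry a raw
# code collapsed into it. The map must remain total over the raw codes and
# surjective onto the 14 groups.
hypertension:
  - hypertension
diabetes:
  - diabetes
chronic_liver_disease:
  - chronic_hepatitis
  - alcoholic_hepatitis
  - hepatic_cirrhosis
gonarthrosis:
  - gonarthrosis
arthritis:
  - degenerative_arthritis
  - rheumatoid_arthritis
spondylosis:
  - disc_disorder
  - other_spondylopathy
cancer:
  - gastric_cancer
  - colorectal_cancer
  - lung_cancer
  - breast_cancer
  - cervical_cancer
  - thyroid_cancer
  - other_cancer
cardiovascular_disease:
  - angina
  - myocardial_infarction
cerebrovascular_disease:
  - cerebral_hemorrhage
  - cerebral_infarction
chronic_respiratory_disease:
  - asthma
  - pulmonary_emphysema
  - copd
  - bronchiectasis
thyroid_disease:
  - hypothyroidism
  - hyperthyroidism
depression:
  - depression
alzheimers_disease:
  - alzheimers_disease
chronic_renal_failure:
  - chronic_renal_failure
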