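# Combined comorbidity score (Gagne et al. 2011, J Clin Epidemiol 64:749-759):
# 20 conditions merging Charlson and Elixhauser systems, with the published
# integer weights. The ICD-9-CM prefix sets below are a simplified,
# representative mapping (not the full published code lists); edit freely —
# the package treats this file as data.
provenance: >
  Gagne JJ, Glynn RJ, Avorn J, Levin R, Schneeweiss S. A combined comorbidity
  score predicted mortality in elderly patients better than existing scores.
  J Clin Epidemiol. 2011;64(7):749-759. Simplified ICD-9-CM prefix mapping.
metastatic_cancer:
  prefixes: ["196", "197", "198", "199"]
  weight: 5
congestive_heart_failure:
  prefixes: ["428"]
  weight: 2
dementia:
  prefixes: ["290", "2941"]
  weight: 2
renal_failure:
  prefixes: ["585", "586"]
  weight: 2
weight_loss:
  prefixes: ["260", "261", "262", "263"]
  weight: 2
hemiplegia:
  prefixes: ["342", "344"]
  weight: 1
alcohol_abuse:
  prefixes: ["303", "3050"]
  weight: 1
any_tumor:
  prefixes: ["153", "162", "174", "185", "200", "201", "202", "203"]
  weight: 1
cardiac_arrhythmia:
  prefixes: ["4273"]
  weight: 1
chronic_pulmonary_disease:
  prefixes: ["491", "492", "496"]
  weight: 1
coagulopathy:
  prefixes: ["286"]
  weight: 1
complicated_diabetes:
  prefixes: ["2504", "2505", "2506", "2507"]
  weight: 1
deficiency_anemia:
  prefixes: ["280", "281"]
  weight: 1
fluid_electrolyte_disorders:
  prefixes: ["276"]
  weight: 1
liver_disease:
  prefixes: ["571"]
  weight: 1
peripheral_vascular_disorder:
  prefixes: ["443", "440"]
  weight: 1
psychosis:
  prefixes: ["295", "297", "298"]
  weight: 1
pulmonary_circulation_disorders:
  prefixes: ["4150", "4151", "416"]
  weight: 1
hiv_aids:
  prefixes: ["042"]
  weight: -1
hypertension:
  prefixes: ["401", "402", "403", "404", "405"]
  weight: -1
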