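# Example CDS rule set: a biomarker alert and a warfarin dosing rule.
- rule_id: braf-v600e-alert
  trigger:
    alias: "BRAF:V600E"
  action: alert
  knowledge_ref: "FDA-qualified melanoma biomarker (BRAF p.V600E)"
  parameters:
    alert_text: "BRAF V600E detected: BRAF/MEK inhibitor therapy may be considered."
- rule_id: warfarin-iwpc-dose
  trigger:
    genotype: true
  action: dose_calculation
  knowledge_ref: "IWPC warfarin dosing algorithm (IWPC-2009)"
  parameters:
    dosing_function: iwpc_warfarin
    age_decades: 6.8
    height_cm: 170
    weight_kg: 70
    race_group: white
    enzyme_inducer: false
    amiodarone: false
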