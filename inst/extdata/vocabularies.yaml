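# Closed vocabularies for enumerated attributes. Editing this file (and
# loading it with loadVocabularies()) extends the permitted value sets; the
# defaults below match the packaged model.
sequence_type: [WGS, WES, panel, targeted, other]
stage: [alignment, realignment_recalibration, variant_calling,
        sequence_annotation, clinical_annotation]
zygosity: [heterozygous, homozygous, hemizygous, unknown]
phasing: [phased, unphased, unknown]
variant_type: [SNV, InDel, CNV, translocation_fusion]
annotation_class: [acmg_actionable, fda_qualified_biomarker, user_defined_biomarker]
msi_status: [MSI-H, MSI-L, MSS, unknown]
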