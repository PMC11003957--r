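# Class labels used throughout: the four consensus molecular subtypes, plus
# the "mixed" outcome that only ensemble-level calls can take.
CMS_CLASSES <- c("CMS1", "CMS2", "CMS3", "CMS4")
CALL_LEVELS <- c(CMS_CLASSES, "mixed")
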