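# canonical channel and class orders used throughout the package
NIRS_CHANNELS <- c("LOEA", "ROEA", "LDT", "RDT", "LES", "RES")
NIRS_CLASSES <- c("NC", "LF", "TR", "SE")
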