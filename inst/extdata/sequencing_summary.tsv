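quantity	value
totalRawReads	110614744
libraries	8
totalCleanReads	94692697
knownMiRNAs	410
homologMiRNAs	752
novelMiRNAs	88
over10kRPM	19
deKnownMiRNAs	221
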