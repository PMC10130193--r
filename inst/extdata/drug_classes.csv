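class,drug
aspirin,aspirin
P2Y12,clopidogrel
P2Y12,ticagrelor
P2Y12,ticlopidine
P2Y12,prasugrel
warfarin,warfarin
DOAC,apixaban
DOAC,dabigatran
DOAC,edoxaban
DOAC,rivaroxaban
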