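synonym,canonical
acetylsalicylic acid,aspirin
clopidogrel sulfate,clopidogrel
ticlopidine hydrochloride,ticlopidine
prasugrel hydrochloride,prasugrel
warfarin potassium,warfarin
dabigatran etexilate methanesulfonate,dabigatran
edoxaban tosylate hydrate,edoxaban
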