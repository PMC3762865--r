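@node	DNAdamage	input
@node	ATM	internal
@node	ATR	internal
@node	CHEK1	internal
@node	CHEK2	internal
@node	AURKA	internal
@node	PTTG1	internal
@node	CDC25A	internal
@node	p53	internal
@node	MDM2	internal
@node	MDM4	internal
@node	MYC	internal
@node	E2F1	internal
@node	FAS	internal
@node	BAX	internal
@node	CDKN1A	internal
@node	p53AIP1	internal
@node	LATS2	internal
@node	apoptosis	output
@node	senescence	output
DNAdamage	activation	ATM
DNAdamage	activation	ATR
DNAdamage	activation	FAS
DNAdamage	inhibition	PTTG1
DNAdamage	inhibition	AURKA
ATM	activation	p53
ATM	activation	CHEK2
ATM	activation	CHEK1
ATR	activation	p53
ATR	activation	CHEK1
CHEK2	activation	p53
CHEK1	inhibition	CDC25A
AURKA	inhibition	p53
p53	activation	MDM2
MDM2	inhibition	p53
MDM2	inhibition	MDM4
MDM4	activation	MDM2
MDM4	inhibition	MDM2
p53	inhibition	MYC
p53	activation	BAX
p53	activation	CDKN1A
p53	activation	p53AIP1
p53	activation	LATS2
p53	activation	FAS
p53	inhibition	PTTG1
MYC	activation	E2F1
E2F1	activation	CHEK2
MYC	activation	FAS
FAS	activation	apoptosis
BAX	activation	apoptosis
p53AIP1	activation	apoptosis
LATS2	activation	apoptosis
CDKN1A	activation	senescence
MYC	inhibition	senescence
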