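compound_id	name	category	superclass	fingerprint
digoxin_analog	digoxin analog (synthetic)	drug	Steroids and steroid derivatives (synthetic)	AAADcf//////////////////////////////////////////////////////////////////AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA==
cortisone_analog	cortisone analog (synthetic)	drug	Steroids and steroid derivatives (synthetic)	AAADcf////////////////////////////////8AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA//////////AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA==
progesterone_analog	progesterone analog (synthetic)	endogenous	Steroids and steroid derivatives (synthetic)	AAADcf////////////////////////////////8AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAP/////////wAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA==
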