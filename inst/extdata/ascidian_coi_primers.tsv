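name	sequence	orientation
AscCOI_F	CCTGATATGGCNTTYCCHCG	forward
AscCOI_R	GCTAAATGHAAHGAAAAAATWGC	reverse
AscCOI2_F	CCDGATATAGCHTTYCCWCG	forward
AscCOI2_R	CYTAAAATACTWGAAACNCTHGC	reverse
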