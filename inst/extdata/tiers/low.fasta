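>low_source
NVQFRWNKERARSSVAITGRPGMYMEESKHASTVFNVDLHACTDEDQCQC
>low_target
NVPVSINTQQPWRCTDMENLVFGLGLYRRHTFWIAKLDNFVATVRMRPLP
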