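>high_source
TPIICGYCGAINCPPCVQCLFVPNKAMEHIIMLSITILKMEWNAGECGNL
>high_target
TPGDVEYMNALACPPGVQCYPVINKAQAKDYILVLGVLWRNPDCYLCGLE
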