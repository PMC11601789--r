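>medium_source
AYCFWPLSLEAAPCMMIDMTIRIYMRNVGIIVVIDVGYISCRKGYFVYEV
>medium_target
WCIPAFSSIHSFEYTSIMVTHSHAMAWRGINVNHHTHTYSDKSDYCSVIM
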