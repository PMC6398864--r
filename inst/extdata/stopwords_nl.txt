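de
het
een
en
van
in
op
met
voor
niet
is
te
dat
die
aan
bij
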