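so
therefore
moreover
everyone
okay
just
like
on the contrary
barely
that
much
first
of
all
them
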