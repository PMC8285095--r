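substance,harm_index
tobacco,37.3
alcohol,56.1
crack_cocaine,79.5
cannabis,25.3
heroin,73.0
powder_cocaine,42.4
methadone_prescribed,24.9
methamphetamine,68.8
amphetamine,40.8
methadone_nonprescribed,24.9
ecstasy,18.5
lsd,15.0
ghb,37.9
ketamine,28.9
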