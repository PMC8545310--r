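pray
for
my
mother
father
flu
fever
cough
breathe
breathing
mask
health
stay
home
safe
hands
wash
virus
corona
quarantine
love
family
friend
work
study
nature
music
sport
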