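# published membership counts of the four most prevalent Lysin A domain organizations
# n_total=224 sequenced mycobacteriophage endolysins
label	size
Org-A	47
Org-I	38
Org-J	31
Org-K	26
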