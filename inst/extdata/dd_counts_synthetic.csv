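cdr_id,tp,tn,fp,fn
rackoff,9,294,106,6
klaassen,29,116,83,8
baorto,70,604,319,22
madsen,28,192,81,19
rondinelli,46,164,82,11
spog_ae,62,122,99,8
hakim,61,186,65,25
suttitossatam,20,600,250,10
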