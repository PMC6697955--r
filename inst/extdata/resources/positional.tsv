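surface	canonical
left	left
right	right
bilateral	bilateral
bilaterally	bilateral
upper	upper
lower	lower
proximal	proximal
distal	distal
anterior	anterior
posterior	posterior
medial	medial
lateral	lateral
dorsal	dorsal
ventral	ventral
superior	superior
inferior	inferior
cranial	cranial
caudal	caudal
deep	deep
superficial	superficial
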