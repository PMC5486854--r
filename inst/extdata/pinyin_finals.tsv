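final	symbols
a	a
o	o
e	e
i	i
u	u
v	v
ai	ai
ei	ei
ao	ao
ou	ou
an	a n
en	e n
ang	a N
eng	e N
ong	o N
er	e r
ia	y a
ie	y E
iao	y ao
iou	y ou
iu	y ou
ian	y E n
in	i n
iang	y a N
ing	i N
iong	y o N
ua	w a
uo	w o
uai	w ai
uei	w ei
ui	w ei
uan	w a n
uen	w e n
un	w e n
uang	w a N
ueng	w e N
ve	y E
van	y E n
vn	v n
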