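symbol	sound_class	manner	place	voiced	height	backness	rounded	long	diphthong
p	consonant	plosive	bilabial	FALSE	none	none	FALSE	FALSE	FALSE
b	consonant	plosive	bilabial	TRUE	none	none	FALSE	FALSE	FALSE
t	consonant	plosive	alveolar	FALSE	none	none	FALSE	FALSE	FALSE
d	consonant	plosive	alveolar	TRUE	none	none	FALSE	FALSE	FALSE
k	consonant	plosive	velar	FALSE	none	none	FALSE	FALSE	FALSE
g	consonant	plosive	velar	TRUE	none	none	FALSE	FALSE	FALSE
m	consonant	nasal	bilabial	TRUE	none	none	FALSE	FALSE	FALSE
n	consonant	nasal	alveolar	TRUE	none	none	FALSE	FALSE	FALSE
N	consonant	nasal	velar	TRUE	none	none	FALSE	FALSE	FALSE
f	consonant	fricative	labiodental	FALSE	none	none	FALSE	FALSE	FALSE
v	consonant	fricative	labiodental	TRUE	none	none	FALSE	FALSE	FALSE
s	consonant	fricative	alveolar	FALSE	none	none	FALSE	FALSE	FALSE
z	consonant	fricative	alveolar	TRUE	none	none	FALSE	FALSE	FALSE
S	consonant	fricative	postalveolar	FALSE	none	none	FALSE	FALSE	FALSE
C	consonant	fricative	palatal	FALSE	none	none	FALSE	FALSE	FALSE
x	consonant	fricative	velar	FALSE	none	none	FALSE	FALSE	FALSE
h	consonant	fricative	glottal	FALSE	none	none	FALSE	FALSE	FALSE
pf	consonant	affricate	labiodental	FALSE	none	none	FALSE	FALSE	FALSE
ts	consonant	affricate	alveolar	FALSE	none	none	FALSE	FALSE	FALSE
tS	consonant	affricate	postalveolar	FALSE	none	none	FALSE	FALSE	FALSE
R	consonant	trill	uvular	TRUE	none	none	FALSE	FALSE	FALSE
l	consonant	lateral	alveolar	TRUE	none	none	FALSE	FALSE	FALSE
j	consonant	approximant	palatal	TRUE	none	none	FALSE	FALSE	FALSE
i:	vowel	none	none	TRUE	close	front	FALSE	TRUE	FALSE
I	vowel	none	none	TRUE	near_close	near_front	FALSE	FALSE	FALSE
y:	vowel	none	none	TRUE	close	front	TRUE	TRUE	FALSE
Y	vowel	none	none	TRUE	near_close	near_front	TRUE	FALSE	FALSE
e:	vowel	none	none	TRUE	close_mid	front	FALSE	TRUE	FALSE
E	vowel	none	none	TRUE	open_mid	front	FALSE	FALSE	FALSE
2:	vowel	none	none	TRUE	close_mid	front	TRUE	TRUE	FALSE
9	vowel	none	none	TRUE	open_mid	front	TRUE	FALSE	FALSE
a	vowel	none	none	TRUE	open	central	FALSE	FALSE	FALSE
a:	vowel	none	none	TRUE	open	central	FALSE	TRUE	FALSE
o:	vowel	none	none	TRUE	close_mid	back	TRUE	TRUE	FALSE
O	vowel	none	none	TRUE	open_mid	back	TRUE	FALSE	FALSE
u:	vowel	none	none	TRUE	close	back	TRUE	TRUE	FALSE
U	vowel	none	none	TRUE	near_close	near_back	TRUE	FALSE	FALSE
@	vowel	none	none	TRUE	mid	central	FALSE	FALSE	FALSE
6	vowel	none	none	TRUE	near_open	central	FALSE	FALSE	FALSE
aI	vowel	none	none	TRUE	open	central	FALSE	FALSE	TRUE
aU	vowel	none	none	TRUE	open	central	FALSE	FALSE	TRUE
OY	vowel	none	none	TRUE	open_mid	back	TRUE	FALSE	TRUE
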