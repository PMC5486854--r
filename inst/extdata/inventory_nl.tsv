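symbol	sound_class	manner	place	voiced	height	backness	rounded	long	diphthong
p	consonant	plosive	bilabial	FALSE	none	none	FALSE	FALSE	FALSE
b	consonant	plosive	bilabial	TRUE	none	none	FALSE	FALSE	FALSE
t	consonant	plosive	alveolar	FALSE	none	none	FALSE	FALSE	FALSE
d	consonant	plosive	alveolar	TRUE	none	none	FALSE	FALSE	FALSE
k	consonant	plosive	velar	FALSE	none	none	FALSE	FALSE	FALSE
m	consonant	nasal	bilabial	TRUE	none	none	FALSE	FALSE	FALSE
n	consonant	nasal	alveolar	TRUE	none	none	FALSE	FALSE	FALSE
N	consonant	nasal	velar	TRUE	none	none	FALSE	FALSE	FALSE
f	consonant	fricative	labiodental	FALSE	none	none	FALSE	FALSE	FALSE
v	consonant	fricative	labiodental	TRUE	none	none	FALSE	FALSE	FALSE
s	consonant	fricative	alveolar	FALSE	none	none	FALSE	FALSE	FALSE
z	consonant	fricative	alveolar	TRUE	none	none	FALSE	FALSE	FALSE
x	consonant	fricative	velar	FALSE	none	none	FALSE	FALSE	FALSE
G	consonant	fricative	velar	TRUE	none	none	FALSE	FALSE	FALSE
S	consonant	fricative	postalveolar	FALSE	none	none	FALSE	FALSE	FALSE
h	consonant	fricative	glottal	TRUE	none	none	FALSE	FALSE	FALSE
r	consonant	trill	alveolar	TRUE	none	none	FALSE	FALSE	FALSE
R	consonant	fricative	uvular	TRUE	none	none	FALSE	FALSE	FALSE
l	consonant	lateral	alveolar	TRUE	none	none	FALSE	FALSE	FALSE
j	consonant	approximant	palatal	TRUE	none	none	FALSE	FALSE	FALSE
w	consonant	approximant	labiodental	TRUE	none	none	FALSE	FALSE	FALSE
i	vowel	none	none	TRUE	close	front	FALSE	FALSE	FALSE
y	vowel	none	none	TRUE	close	front	TRUE	FALSE	FALSE
I	vowel	none	none	TRUE	near_close	near_front	FALSE	FALSE	FALSE
Y	vowel	none	none	TRUE	near_close	near_front	TRUE	FALSE	FALSE
e:	vowel	none	none	TRUE	close_mid	front	FALSE	TRUE	FALSE
2:	vowel	none	none	TRUE	close_mid	front	TRUE	TRUE	FALSE
E	vowel	none	none	TRUE	open_mid	front	FALSE	FALSE	FALSE
a	vowel	none	none	TRUE	open	central	FALSE	FALSE	FALSE
a:	vowel	none	none	TRUE	open	central	FALSE	TRUE	FALSE
A	vowel	none	none	TRUE	open	back	FALSE	FALSE	FALSE
O	vowel	none	none	TRUE	open_mid	back	TRUE	FALSE	FALSE
o:	vowel	none	none	TRUE	close_mid	back	TRUE	TRUE	FALSE
u	vowel	none	none	TRUE	close	back	TRUE	FALSE	FALSE
@	vowel	none	none	TRUE	mid	central	FALSE	FALSE	FALSE
Ei	vowel	none	none	TRUE	open_mid	front	FALSE	FALSE	TRUE
9y	vowel	none	none	TRUE	open_mid	front	TRUE	FALSE	TRUE
Au	vowel	none	none	TRUE	open	back	FALSE	FALSE	TRUE
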