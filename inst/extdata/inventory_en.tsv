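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
T	consonant	fricative	dental	FALSE	none	none	FALSE	FALSE	FALSE
D	consonant	fricative	dental	TRUE	none	none	FALSE	FALSE	FALSE
s	consonant	fricative	alveolar	FALSE	none	none	FALSE	FALSE	FALSE
z	consonant	fricative	alveolar	TRUE	none	none	FALSE	FALSE	FALSE
S	consonant	fricative	postalveolar	FALSE	none	none	FALSE	FALSE	FALSE
Z	consonant	fricative	postalveolar	TRUE	none	none	FALSE	FALSE	FALSE
h	consonant	fricative	glottal	FALSE	none	none	FALSE	FALSE	FALSE
tS	consonant	affricate	postalveolar	FALSE	none	none	FALSE	FALSE	FALSE
dZ	consonant	affricate	postalveolar	TRUE	none	none	FALSE	FALSE	FALSE
l	consonant	lateral	alveolar	TRUE	none	none	FALSE	FALSE	FALSE
r	consonant	approximant	alveolar	TRUE	none	none	FALSE	FALSE	FALSE
j	consonant	approximant	palatal	TRUE	none	none	FALSE	FALSE	FALSE
w	consonant	approximant	velar	TRUE	none	none	TRUE	FALSE	FALSE
i	vowel	none	none	TRUE	close	front	FALSE	FALSE	FALSE
i:	vowel	none	none	TRUE	close	front	FALSE	TRUE	FALSE
I	vowel	none	none	TRUE	near_close	near_front	FALSE	FALSE	FALSE
E	vowel	none	none	TRUE	open_mid	front	FALSE	FALSE	FALSE
ae	vowel	none	none	TRUE	near_open	front	FALSE	FALSE	FALSE
V	vowel	none	none	TRUE	open_mid	back	FALSE	FALSE	FALSE
A:	vowel	none	none	TRUE	open	back	FALSE	TRUE	FALSE
O:	vowel	none	none	TRUE	open_mid	back	TRUE	TRUE	FALSE
U	vowel	none	none	TRUE	near_close	near_back	TRUE	FALSE	FALSE
u:	vowel	none	none	TRUE	close	back	TRUE	TRUE	FALSE
@	vowel	none	none	TRUE	mid	central	FALSE	FALSE	FALSE
3:	vowel	none	none	TRUE	open_mid	central	FALSE	TRUE	FALSE
eI	vowel	none	none	TRUE	close_mid	front	FALSE	FALSE	TRUE
aI	vowel	none	none	TRUE	open	front	FALSE	FALSE	TRUE
OI	vowel	none	none	TRUE	open_mid	back	TRUE	FALSE	TRUE
aU	vowel	none	none	TRUE	open	back	FALSE	FALSE	TRUE
oU	vowel	none	none	TRUE	close_mid	back	TRUE	FALSE	TRUE
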