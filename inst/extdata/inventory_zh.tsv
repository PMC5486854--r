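symbol	sound_class	manner	place	voiced	height	backness	rounded	long	diphthong
b	consonant	plosive	bilabial	TRUE	none	none	FALSE	FALSE	FALSE
p	consonant	plosive	bilabial	FALSE	none	none	FALSE	FALSE	FALSE
m	consonant	nasal	bilabial	TRUE	none	none	FALSE	FALSE	FALSE
f	consonant	fricative	labiodental	FALSE	none	none	FALSE	FALSE	FALSE
d	consonant	plosive	alveolar	TRUE	none	none	FALSE	FALSE	FALSE
t	consonant	plosive	alveolar	FALSE	none	none	FALSE	FALSE	FALSE
n	consonant	nasal	alveolar	TRUE	none	none	FALSE	FALSE	FALSE
l	consonant	lateral	alveolar	TRUE	none	none	FALSE	FALSE	FALSE
g	consonant	plosive	velar	TRUE	none	none	FALSE	FALSE	FALSE
k	consonant	plosive	velar	FALSE	none	none	FALSE	FALSE	FALSE
h	consonant	fricative	glottal	FALSE	none	none	FALSE	FALSE	FALSE
j	consonant	affricate	palatal	TRUE	none	none	FALSE	FALSE	FALSE
q	consonant	affricate	palatal	FALSE	none	none	FALSE	FALSE	FALSE
x	consonant	fricative	palatal	FALSE	none	none	FALSE	FALSE	FALSE
zh	consonant	affricate	postalveolar	TRUE	none	none	FALSE	FALSE	FALSE
ch	consonant	affricate	postalveolar	FALSE	none	none	FALSE	FALSE	FALSE
sh	consonant	fricative	postalveolar	FALSE	none	none	FALSE	FALSE	FALSE
r	consonant	approximant	postalveolar	TRUE	none	none	FALSE	FALSE	FALSE
z	consonant	affricate	alveolar	TRUE	none	none	FALSE	FALSE	FALSE
c	consonant	affricate	alveolar	FALSE	none	none	FALSE	FALSE	FALSE
s	consonant	fricative	alveolar	FALSE	none	none	FALSE	FALSE	FALSE
w	consonant	approximant	velar	TRUE	none	none	TRUE	FALSE	FALSE
y	consonant	approximant	palatal	TRUE	none	none	FALSE	FALSE	FALSE
N	consonant	nasal	velar	TRUE	none	none	FALSE	FALSE	FALSE
a	vowel	none	none	TRUE	open	central	FALSE	FALSE	FALSE
o	vowel	none	none	TRUE	mid	back	TRUE	FALSE	FALSE
e	vowel	none	none	TRUE	mid	back	FALSE	FALSE	FALSE
E	vowel	none	none	TRUE	mid	front	FALSE	FALSE	FALSE
i	vowel	none	none	TRUE	close	front	FALSE	FALSE	FALSE
u	vowel	none	none	TRUE	close	back	TRUE	FALSE	FALSE
v	vowel	none	none	TRUE	close	front	TRUE	FALSE	FALSE
ai	vowel	none	none	TRUE	open	central	FALSE	FALSE	TRUE
ei	vowel	none	none	TRUE	mid	front	FALSE	FALSE	TRUE
ao	vowel	none	none	TRUE	open	central	FALSE	FALSE	TRUE
ou	vowel	none	none	TRUE	mid	back	TRUE	FALSE	TRUE
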