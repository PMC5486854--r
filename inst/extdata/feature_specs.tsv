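name	family	predicate	statistic	languages
n_nasal	word_count	manner=nasal	count	en,nl,de,zh
n_plosive	word_count	manner=plosive	count	en,nl,de,zh
n_fricative	word_count	manner=fricative	count	en,nl,de,zh
n_affricate	word_count	manner=affricate	count	en,nl,de,zh
n_approximant	word_count	manner=approximant	count	en,nl,de,zh
n_lateral	word_count	manner=lateral	count	en,nl,de,zh
n_trill	word_count	manner=trill	count	nl,de
n_bilabial	word_count	place=bilabial	count	en,nl,de,zh
n_labiodental	word_count	place=labiodental	count	en,nl,de,zh
n_dental	word_count	place=dental	count	en
n_alveolar	word_count	place=alveolar	count	en,nl,de,zh
n_postalveolar	word_count	place=postalveolar	count	en,nl,de,zh
n_palatal	word_count	place=palatal	count	en,nl,de,zh
n_velar	word_count	place=velar	count	en,nl,de,zh
n_uvular	word_count	place=uvular	count	nl,de
n_glottal	word_count	place=glottal	count	en,nl,de,zh
n_voiced_consonant	word_count	voiced_consonant	count	en,nl,de,zh
n_consonant	word_count	sound_class=consonant	count	en,nl,de,zh
n_vowel	word_count	sound_class=vowel	count	en,nl,de,zh
n_long_vowel	word_count	long_vowel	count	en,nl,de,zh
n_diphthong	word_count	diphthong	count	en,nl,de,zh
n_rounded_vowel	word_count	rounded_vowel	count	en,nl,de,zh
n_phonemes	word_count	any	count	en,nl,de,zh
p_nasal	word_proportion	manner=nasal	proportion	en,nl,de,zh
p_plosive	word_proportion	manner=plosive	proportion	en,nl,de,zh
p_fricative	word_proportion	manner=fricative	proportion	en,nl,de,zh
p_affricate	word_proportion	manner=affricate	proportion	en,nl,de,zh
p_approximant	word_proportion	manner=approximant	proportion	en,nl,de,zh
p_lateral	word_proportion	manner=lateral	proportion	en,nl,de,zh
p_trill	word_proportion	manner=trill	proportion	nl,de
p_bilabial	word_proportion	place=bilabial	proportion	en,nl,de,zh
p_labiodental	word_proportion	place=labiodental	proportion	en,nl,de,zh
p_dental	word_proportion	place=dental	proportion	en
p_alveolar	word_proportion	place=alveolar	proportion	en,nl,de,zh
p_postalveolar	word_proportion	place=postalveolar	proportion	en,nl,de,zh
p_palatal	word_proportion	place=palatal	proportion	en,nl,de,zh
p_velar	word_proportion	place=velar	proportion	en,nl,de,zh
p_uvular	word_proportion	place=uvular	proportion	nl,de
p_glottal	word_proportion	place=glottal	proportion	en,nl,de,zh
p_voiced_consonant	word_proportion	voiced_consonant	proportion	en,nl,de,zh
p_consonant	word_proportion	sound_class=consonant	proportion	en,nl,de,zh
p_vowel	word_proportion	sound_class=vowel	proportion	en,nl,de,zh
p_long_vowel	word_proportion	long_vowel	proportion	en,nl,de,zh
p_diphthong	word_proportion	diphthong	proportion	en,nl,de,zh
p_rounded_vowel	word_proportion	rounded_vowel	proportion	en,nl,de,zh
ons_nasal	onset	manner=nasal	count	en,nl,de,zh
ons_plosive	onset	manner=plosive	count	en,nl,de,zh
ons_fricative	onset	manner=fricative	count	en,nl,de,zh
ons_affricate	onset	manner=affricate	count	en,nl,de,zh
ons_approximant	onset	manner=approximant	count	en,nl,de,zh
ons_lateral	onset	manner=lateral	count	en,nl,de,zh
ons_trill	onset	manner=trill	count	nl,de
ons_bilabial	onset	place=bilabial	count	en,nl,de,zh
ons_labiodental	onset	place=labiodental	count	en,nl,de,zh
ons_dental	onset	place=dental	count	en
ons_alveolar	onset	place=alveolar	count	en,nl,de,zh
ons_postalveolar	onset	place=postalveolar	count	en,nl,de,zh
ons_palatal	onset	place=palatal	count	en,nl,de,zh
ons_velar	onset	place=velar	count	en,nl,de,zh
ons_uvular	onset	place=uvular	count	nl,de
ons_glottal	onset	place=glottal	count	en,nl,de,zh
ons_voiced_consonant	onset	voiced_consonant	count	en,nl,de,zh
ons_consonant	onset	sound_class=consonant	count	en,nl,de,zh
ons_vowel	onset	sound_class=vowel	count	en,nl,de,zh
ons_long_vowel	onset	long_vowel	count	en,nl,de,zh
ons_diphthong	onset	diphthong	count	en,nl,de,zh
ons_rounded_vowel	onset	rounded_vowel	count	en,nl,de,zh
nasal_first	first_consonant	manner=nasal	indicator	en,nl,de,zh
fc_plosive	first_consonant	manner=plosive	indicator	en,nl,de,zh
fc_fricative	first_consonant	manner=fricative	indicator	en,nl,de,zh
fc_affricate	first_consonant	manner=affricate	indicator	en,nl,de,zh
fc_approximant	first_consonant	manner=approximant	indicator	en,nl,de,zh
fc_lateral	first_consonant	manner=lateral	indicator	en,nl,de,zh
fc_trill	first_consonant	manner=trill	indicator	nl,de
fc_bilabial	first_consonant	place=bilabial	indicator	en,nl,de,zh
fc_labiodental	first_consonant	place=labiodental	indicator	en,nl,de,zh
fc_dental	first_consonant	place=dental	indicator	en
fc_alveolar	first_consonant	place=alveolar	indicator	en,nl,de,zh
fc_postalveolar	first_consonant	place=postalveolar	indicator	en,nl,de,zh
fc_palatal	first_consonant	place=palatal	indicator	en,nl,de,zh
fc_velar	first_consonant	place=velar	indicator	en,nl,de,zh
fc_uvular	first_consonant	place=uvular	indicator	nl,de
fc_glottal	first_consonant	place=glottal	indicator	en,nl,de,zh
fc_voiced_consonant	first_consonant	voiced_consonant	indicator	en,nl,de,zh
v1_height_close	vowel	height=close	indicator	en,nl,de,zh
v1_height_near_close	vowel	height=near_close	indicator	en,nl,de,zh
v1_height_close_mid	vowel	height=close_mid	indicator	en,nl,de
v1_height_mid	vowel	height=mid	indicator	en,nl,de,zh
v1_height_open_mid	vowel	height=open_mid	indicator	en,nl,de
v1_height_near_open	vowel	height=near_open	indicator	en,nl,de,zh
v1_height_open	vowel	height=open	indicator	en,nl,de,zh
v1_back_front	vowel	backness=front	indicator	en,nl,de,zh
v1_back_near_front	vowel	backness=near_front	indicator	en,nl,de
v1_back_central	vowel	backness=central	indicator	en,nl,de,zh
v1_back_near_back	vowel	backness=near_back	indicator	en,nl,de
v1_back_back	vowel	backness=back	indicator	en,nl,de,zh
v1_rounded	vowel	v1_rounded	indicator	en,nl,de,zh
v1_long	vowel	v1_long	indicator	en,nl,de,zh
v1_diphthong	vowel	v1_diphthong	indicator	en,nl,de,zh
tone_1	vowel	tone=1	indicator	zh
tone_2	vowel	tone=2	indicator	zh
tone_3	vowel	tone=3	indicator	zh
tone_4	vowel	tone=4	indicator	zh
tone_5	vowel	tone=5	indicator	zh
tone_mean	vowel	tone_mean	level	zh
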