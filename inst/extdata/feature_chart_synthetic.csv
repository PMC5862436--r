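symbol,absorbed_into,sonorant,syllabic,consonantal,continuant,nasal,high,low,back,round,anterior,coronal,voiced,class,ipa_radical,ipa_dorsal,ipa_coronal,ipa_labial,ipa_plosive,ipa_fricative,ipa_liquid,ipa_nasal,ipa_voiced,ipa_open,ipa_mid,ipa_close,ipa_round,ipa_back
i,,1,1,0,1,0,1,0,0,0,0,0,1,vowel,0,0,0,0,0,0,0,0,1,0,0,1,0,0
y,,1,1,0,1,0,1,0,0,1,0,0,1,vowel,0,0,0,0,0,0,0,0,1,0,0,1,1,0
u,,1,1,0,1,0,1,0,1,1,0,0,1,vowel,0,0,0,0,0,0,0,0,1,0,0,1,1,1
e,,1,1,0,1,0,0,0,0,0,0,0,1,vowel,0,0,0,0,0,0,0,0,1,0,1,0,0,0
ø,,1,1,0,1,0,0,0,0,1,0,0,1,vowel,0,0,0,0,0,0,0,0,1,0,1,0,1,0
ə,,1,1,0,1,0,0,0,1,0,0,0,1,vowel,0,0,0,0,0,0,0,0,1,0,1,0,0,1
o,,1,1,0,1,0,0,0,1,1,0,0,1,vowel,0,0,0,0,0,0,0,0,1,0,1,0,1,1
a,,1,1,0,1,0,0,1,0,0,0,0,1,vowel,0,0,0,0,0,0,0,0,1,1,0,0,0,0
ɑ,,1,1,0,1,0,0,1,1,0,0,0,1,vowel,0,0,0,0,0,0,0,0,1,1,0,0,0,1
p,,0,0,1,0,0,0,0,0,0,1,0,0,consonant,0,0,0,1,1,0,0,0,0,0,0,0,0,0
b,,0,0,1,0,0,0,0,0,0,1,0,1,consonant,0,0,0,1,1,0,0,0,1,0,0,0,0,0
t,,0,0,1,0,0,0,0,0,0,1,1,0,consonant,0,0,1,0,1,0,0,0,0,0,0,0,0,0
d,,0,0,1,0,0,0,0,0,0,1,1,1,consonant,0,0,1,0,1,0,0,0,1,0,0,0,0,0
k,,0,0,1,0,0,1,0,1,0,0,0,0,consonant,0,1,0,0,1,0,0,0,0,0,0,0,0,0
g,,0,0,1,0,0,1,0,1,0,0,0,1,consonant,0,1,0,0,1,0,0,0,1,0,0,0,0,0
c,,0,0,1,0,0,1,0,0,0,0,0,0,consonant,0,1,0,0,1,0,0,0,0,0,0,0,0,0
q,,0,0,1,0,0,0,0,1,0,0,0,0,consonant,0,1,0,0,1,0,0,0,0,0,0,0,0,0
ʔ,,0,0,1,0,0,0,0,0,0,0,0,0,consonant,1,0,0,0,1,0,0,0,0,0,0,0,0,0
f,,0,0,1,1,0,0,0,0,0,1,0,0,consonant,0,0,0,1,0,1,0,0,0,0,0,0,0,0
v,,0,0,1,1,0,0,0,0,0,1,0,1,consonant,0,0,0,1,0,1,0,0,1,0,0,0,0,0
s,,0,0,1,1,0,0,0,0,0,1,1,0,consonant,0,0,1,0,0,1,0,0,0,0,0,0,0,0
z,,0,0,1,1,0,0,0,0,0,1,1,1,consonant,0,0,1,0,0,1,0,0,1,0,0,0,0,0
ʃ,,0,0,1,1,0,0,0,0,0,0,1,0,consonant,0,0,1,0,0,1,0,0,0,0,0,0,0,0
ʒ,,0,0,1,1,0,0,0,0,0,0,1,1,consonant,0,0,1,0,0,1,0,0,1,0,0,0,0,0
x,,0,0,1,1,0,1,0,1,0,0,0,0,consonant,0,1,0,0,0,1,0,0,0,0,0,0,0,0
h,,0,0,1,1,0,0,0,0,0,0,0,0,consonant,1,0,0,0,0,1,0,0,0,0,0,0,0,0
m,,1,0,1,0,1,0,0,0,0,1,0,1,consonant,0,0,0,1,0,0,0,1,1,0,0,0,0,0
n,,1,0,1,0,1,0,0,0,0,1,1,1,consonant,0,0,1,0,0,0,0,1,1,0,0,0,0,0
ɲ,,1,0,1,0,1,1,0,0,0,0,1,1,consonant,0,0,1,0,0,0,0,1,1,0,0,0,0,0
ŋ,,1,0,1,0,1,1,0,1,0,0,0,1,consonant,0,1,0,0,0,0,0,1,1,0,0,0,0,0
l,,1,0,1,1,0,0,0,0,0,1,1,1,consonant,0,0,1,0,0,0,1,0,1,0,0,0,0,0
r,,1,0,1,1,0,0,0,0,0,0,1,1,consonant,0,0,1,0,0,0,1,0,1,0,0,0,0,0
ʁ,,1,0,1,1,0,0,0,1,0,0,0,1,consonant,0,1,0,0,0,0,1,0,1,0,0,0,0,0
j,,1,0,1,1,0,1,0,0,0,0,0,1,consonant,0,1,0,0,0,0,1,0,1,0,0,0,0,0
w,,1,0,1,1,0,1,0,1,1,0,0,1,consonant,0,1,0,0,0,0,1,0,1,0,0,0,0,0
ɪ,i,1,1,0,1,0,1,0,0,0,0,0,1,vowel,0,0,0,0,0,0,0,0,1,0,0,1,0,0
ʏ,y,1,1,0,1,0,1,0,0,1,0,0,1,vowel,0,0,0,0,0,0,0,0,1,0,0,1,1,0
ʊ,u,1,1,0,1,0,1,0,1,1,0,0,1,vowel,0,0,0,0,0,0,0,0,1,0,0,1,1,1
ɛ,e,1,1,0,1,0,0,0,0,0,0,0,1,vowel,0,0,0,0,0,0,0,0,1,0,1,0,0,0
œ,ø,1,1,0,1,0,0,0,0,1,0,0,1,vowel,0,0,0,0,0,0,0,0,1,0,1,0,1,0
ʌ,ə,1,1,0,1,0,0,0,1,0,0,0,1,vowel,0,0,0,0,0,0,0,0,1,0,1,0,0,1
ɔ,o,1,1,0,1,0,0,0,1,1,0,0,1,vowel,0,0,0,0,0,0,0,0,1,0,1,0,1,1
æ,a,1,1,0,1,0,0,1,0,0,0,0,1,vowel,0,0,0,0,0,0,0,0,1,1,0,0,0,0
ɐ,a,1,1,0,1,0,0,1,0,0,0,0,1,vowel,0,0,0,0,0,0,0,0,1,1,0,0,0,0
ɒ,ɑ,1,1,0,1,0,0,1,1,0,0,0,1,vowel,0,0,0,0,0,0,0,0,1,1,0,0,0,1
ɨ,i,1,1,0,1,0,1,0,0,0,0,0,1,vowel,0,0,0,0,0,0,0,0,1,0,0,1,0,0
θ,s,0,0,1,1,0,0,0,0,0,1,1,0,consonant,0,0,1,0,0,1,0,0,0,0,0,0,0,0
ð,z,0,0,1,1,0,0,0,0,0,1,1,1,consonant,0,0,1,0,0,1,0,0,1,0,0,0,0,0
ç,ʃ,0,0,1,1,0,0,0,0,0,0,1,0,consonant,0,0,1,0,0,1,0,0,0,0,0,0,0,0
ɣ,ʁ,1,0,1,1,0,0,0,1,0,0,0,1,consonant,0,1,0,0,0,0,1,0,1,0,0,0,0,0
ɹ,r,1,0,1,1,0,0,0,0,0,0,1,1,consonant,0,0,1,0,0,0,1,0,1,0,0,0,0,0
ɾ,r,1,0,1,1,0,0,0,0,0,0,1,1,consonant,0,0,1,0,0,0,1,0,1,0,0,0,0,0
ʎ,j,1,0,1,1,0,1,0,0,0,0,0,1,consonant,0,1,0,0,0,0,1,0,1,0,0,0,0,0
á,a,1,1,0,1,0,0,1,0,0,0,0,1,vowel,0,0,0,0,0,0,0,0,1,1,0,0,0,0
à,a,1,1,0,1,0,0,1,0,0,0,0,1,vowel,0,0,0,0,0,0,0,0,1,1,0,0,0,0
â,a,1,1,0,1,0,0,1,0,0,0,0,1,vowel,0,0,0,0,0,0,0,0,1,1,0,0,0,0
ä,a,1,1,0,1,0,0,1,0,0,0,0,1,vowel,0,0,0,0,0,0,0,0,1,1,0,0,0,0
ã,a,1,1,0,1,0,0,1,0,0,0,0,1,vowel,0,0,0,0,0,0,0,0,1,1,0,0,0,0
å,a,1,1,0,1,0,0,1,0,0,0,0,1,vowel,0,0,0,0,0,0,0,0,1,1,0,0,0,0
é,e,1,1,0,1,0,0,0,0,0,0,0,1,vowel,0,0,0,0,0,0,0,0,1,0,1,0,0,0
è,e,1,1,0,1,0,0,0,0,0,0,0,1,vowel,0,0,0,0,0,0,0,0,1,0,1,0,0,0
ê,e,1,1,0,1,0,0,0,0,0,0,0,1,vowel,0,0,0,0,0,0,0,0,1,0,1,0,0,0
ë,e,1,1,0,1,0,0,0,0,0,0,0,1,vowel,0,0,0,0,0,0,0,0,1,0,1,0,0,0
í,i,1,1,0,1,0,1,0,0,0,0,0,1,vowel,0,0,0,0,0,0,0,0,1,0,0,1,0,0
ì,i,1,1,0,1,0,1,0,0,0,0,0,1,vowel,0,0,0,0,0,0,0,0,1,0,0,1,0,0
î,i,1,1,0,1,0,1,0,0,0,0,0,1,vowel,0,0,0,0,0,0,0,0,1,0,0,1,0,0
ï,i,1,1,0,1,0,1,0,0,0,0,0,1,vowel,0,0,0,0,0,0,0,0,1,0,0,1,0,0
ó,o,1,1,0,1,0,0,0,1,1,0,0,1,vowel,0,0,0,0,0,0,0,0,1,0,1,0,1,1
ò,o,1,1,0,1,0,0,0,1,1,0,0,1,vowel,0,0,0,0,0,0,0,0,1,0,1,0,1,1
ô,o,1,1,0,1,0,0,0,1,1,0,0,1,vowel,0,0,0,0,0,0,0,0,1,0,1,0,1,1
ö,o,1,1,0,1,0,0,0,1,1,0,0,1,vowel,0,0,0,0,0,0,0,0,1,0,1,0,1,1
õ,o,1,1,0,1,0,0,0,1,1,0,0,1,vowel,0,0,0,0,0,0,0,0,1,0,1,0,1,1
ú,u,1,1,0,1,0,1,0,1,1,0,0,1,vowel,0,0,0,0,0,0,0,0,1,0,0,1,1,1
ù,u,1,1,0,1,0,1,0,1,1,0,0,1,vowel,0,0,0,0,0,0,0,0,1,0,0,1,1,1
û,u,1,1,0,1,0,1,0,1,1,0,0,1,vowel,0,0,0,0,0,0,0,0,1,0,0,1,1,1
ü,u,1,1,0,1,0,1,0,1,1,0,0,1,vowel,0,0,0,0,0,0,0,0,1,0,0,1,1,1
ñ,ɲ,1,0,1,0,1,1,0,0,0,0,1,1,consonant,0,0,1,0,0,0,0,1,1,0,0,0,0,0
š,ʃ,0,0,1,1,0,0,0,0,0,0,1,0,consonant,0,0,1,0,0,1,0,0,0,0,0,0,0,0
ž,ʒ,0,0,1,1,0,0,0,0,0,0,1,1,consonant,0,0,1,0,0,1,0,0,1,0,0,0,0,0
č,ʃ,0,0,1,1,0,0,0,0,0,0,1,0,consonant,0,0,1,0,0,1,0,0,0,0,0,0,0,0
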