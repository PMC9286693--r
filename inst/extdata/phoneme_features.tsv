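symbol	type	place_labial	place_dental	place_alveolar	place_postalveolar	place_velar	place_glottal	manner_plosive	manner_nasal	manner_fricative	manner_affricate	manner_approximant	manner_lateral	manner_aspirated	voiced	height_high	height_midhigh	height_midlow	height_low	back_front	back_central	back_back	round_long
p	C	1	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
b	C	1	0	0	0	0	0	1	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0
m	C	1	0	0	0	0	0	0	1	0	0	0	0	0	1	0	0	0	0	0	0	0	0
f	C	1	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0
v	C	1	0	0	0	0	0	0	0	1	0	0	0	0	1	0	0	0	0	0	0	0	0
w	C	1	0	0	0	0	0	0	0	0	0	1	0	0	1	0	0	0	0	0	0	0	0
ph	C	1	0	0	0	0	0	1	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0
T	C	0	1	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0
D	C	0	1	0	0	0	0	0	0	1	0	0	0	0	1	0	0	0	0	0	0	0	0
t	C	0	0	1	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
d	C	0	0	1	0	0	0	1	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0
n	C	0	0	1	0	0	0	0	1	0	0	0	0	0	1	0	0	0	0	0	0	0	0
s	C	0	0	1	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0
z	C	0	0	1	0	0	0	0	0	1	0	0	0	0	1	0	0	0	0	0	0	0	0
l	C	0	0	1	0	0	0	0	0	0	0	0	1	0	1	0	0	0	0	0	0	0	0
r	C	0	0	1	0	0	0	0	0	0	0	1	0	0	1	0	0	0	0	0	0	0	0
th	C	0	0	1	0	0	0	1	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0
S	C	0	0	0	1	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0
Z	C	0	0	0	1	0	0	0	0	1	0	0	0	0	1	0	0	0	0	0	0	0	0
tS	C	0	0	0	1	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0
dZ	C	0	0	0	1	0	0	0	0	0	1	0	0	0	1	0	0	0	0	0	0	0	0
j	C	0	0	0	1	0	0	0	0	0	0	1	0	0	1	0	0	0	0	0	0	0	0
k	C	0	0	0	0	1	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
g	C	0	0	0	0	1	0	1	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0
N	C	0	0	0	0	1	0	0	1	0	0	0	0	0	1	0	0	0	0	0	0	0	0
x	C	0	0	0	0	1	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0
kh	C	0	0	0	0	1	0	1	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0
h	C	0	0	0	0	0	1	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0
i	V	0	0	0	0	0	0	0	0	0	0	0	0	0	1	1	0	0	0	1	0	0	1
I	V	0	0	0	0	0	0	0	0	0	0	0	0	0	1	1	0	0	0	1	0	0	0
y	V	0	0	0	0	0	0	0	0	0	0	0	0	0	1	1	0	0	0	1	1	0	1
u	V	0	0	0	0	0	0	0	0	0	0	0	0	0	1	1	0	0	0	0	0	1	1
U	V	0	0	0	0	0	0	0	0	0	0	0	0	0	1	1	0	0	0	0	0	1	0
e	V	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	1	0	0	1	0	0	1
E	V	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	1	0	1	0	0	0
2	V	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	1	0	0	1	1	0	1
@	V	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	1	0	0	0	1	0	0
{	V	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	1	1	0	0	0
a	V	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	1	0	1	0	1
A	V	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	1	0	0	1	0
O	V	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	1	0	0	0	1	0
o	V	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	1	0	0	0	0	1	1
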