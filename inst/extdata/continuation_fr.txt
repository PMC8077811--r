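# French prepositions and conjunctions blocking a sentence boundary
# (one word per line, lowercase, post-normalization spelling)
a
de
du
des
d
l
en
par
pour
sur
sous
avec
sans
dans
entre
vers
chez
avant
apres
depuis
pendant
durant
selon
contre
malgre
jusque
jusqu
et
ou
mais
donc
or
ni
car
puis
si
que
qu
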