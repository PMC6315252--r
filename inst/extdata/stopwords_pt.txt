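# Portuguese function words suppressed from word-frequency tables.
a
à
às
ao
aos
as
o
os
um
uma
uns
umas
de
do
da
dos
das
em
no
na
nos
nas
num
numa
por
pelo
pela
pelos
pelas
para
pra
com
sem
sobre
sob
que
e
ou
mas
se
não
sim
é
são
foi
ser
era
está
estão
estar
tem
têm
ter
há
já
mais
menos
muito
muita
muitos
muitas
como
quando
onde
quem
qual
quais
este
esta
isto
esse
essa
isso
aquele
aquela
aquilo
seu
sua
seus
suas
meu
minha
nosso
nossa
você
vocês
eu
ele
ela
eles
elas
nós
até
também
depois
antes
entre
contra
durante
cada
todo
toda
todos
todas
outro
outra
outros
outras
mesmo
mesma
ainda
aqui
ali
lá
então
assim
só
nem
ser
seja
foi
ao
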