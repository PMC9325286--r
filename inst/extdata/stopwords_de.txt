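# General-purpose German stop words (one per line).
# Negations are present here on purpose: the package removes them from the
# active stop list programmatically so that they survive filtering.
aber
alle
allem
allen
aller
alles
als
also
am
an
ander
andere
anderem
anderen
anderer
anderes
auch
auf
aus
bei
beim
bin
bis
bist
da
damit
dann
das
dass
dem
den
denn
der
des
dessen
die
dies
diese
diesem
diesen
dieser
dieses
doch
dort
du
durch
ein
eine
einem
einen
einer
eines
einig
einige
einigem
einigen
einiger
einiges
er
es
etwas
euer
eure
für
gegen
gewesen
hab
habe
haben
hat
hatte
hatten
hier
hin
hinter
ich
ihm
ihn
ihnen
ihr
ihre
im
in
indem
ins
ist
ja
jede
jedem
jeden
jeder
jedes
jene
jenem
jenen
jener
jenes
kann
kein
keine
keinem
keinen
keiner
keines
können
könnte
machen
man
manche
manchem
manchen
mancher
manches
mein
meine
mit
muss
musste
nach
nicht
nichts
noch
nun
nur
ob
oder
ohne
sehr
sein
seine
seinem
seinen
seiner
seines
selbst
sich
sie
sind
so
solche
solchem
solchen
solcher
solches
soll
sollte
sondern
sonst
über
um
und
uns
unser
unsere
unter
viel
vom
von
vor
war
waren
warst
was
weg
weil
weiter
welche
welchem
welchen
welcher
welches
wenn
werde
werden
wie
wieder
will
wir
wird
wirst
wo
wollen
wollte
während
würde
würden
zu
zum
zur
zwar
zwischen
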