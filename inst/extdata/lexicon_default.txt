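# Default interaction-keyword lexicon.
# Entries are raw lowercase words, one per line; they are Porter-stemmed at
# load time, so inflected variants that share a stem need not be repeated.
# Sections:
#   [keywords]     words that may be selected as the instance keyword
#   [iverb]        interaction verbs (used by the structure patterns)
#   [inoun]        interaction nouns (used by the structure patterns)
#   [second]       the seven second keywords
#   [negative]     negation cues
#   [conjunctive]  the sixteen conjunctive words
#   [condition]    assumption/condition cues
#   [prepositions] closed preposition set
[keywords]
abolish
acetylate
activate
adhere
affect
aggregate
antagonize
assemble
assembly
associate
association
attach
attachment
augment
bind
binding
block
bound
catalyze
cleave
cleavage
colocalize
combine
communicate
compete
complex
conjugate
connect
contact
contain
control
cooperate
couple
crosslink
degrade
degradation
depend
dependence
dephosphorylate
destabilize
dimerize
dimerization
dissociate
dissociation
disrupt
downregulate
drive
driven
elevate
eliminate
encode
enhance
expression
facilitate
form
formation
glycosylate
heterodimerize
hydrolyze
impair
improve
inactivate
induce
induction
influence
inhibit
inhibition
initiate
interact
interaction
interfere
involve
ligate
ligation
link
linkage
localize
mediate
methylate
modify
modification
modulate
modulation
neutralize
overexpress
participate
perturb
phosphorylate
phosphorylation
precipitate
prevent
promote
react
reaction
recognize
recognition
recruit
recruitment
reduce
regulate
regulation
relate
relation
release
repress
repression
require
respond
response
restore
sequester
signal
stabilize
stabilization
stimulate
stimulation
substitute
suppress
suppression
synergize
target
tether
transactivate
transduce
transcribe
translocate
trigger
ubiquitinate
upregulate
known
abrogate
accelerate
agonist
amplify
anchor
antagonist
antagonize
arrest
attenuate
autophosphorylate
bridge
chaperone
coactivate
coexpress
cofactor
coimmunoprecipitate
compete
conjugation
coprecipitate
copurify
cosediment
crosslink
deacetylate
demethylate
dephosphorylation
deplete
derepress
desensitize
dock
effector
elicit
engage
escort
exchange
fuse
fusion
homodimerize
hydroxylate
immunoprecipitate
import
inactivation
interconnect
isomerize
ligand
myristoylate
nitrosylate
nucleate
occlude
oligomerize
oppose
oxidize
pair
palmitoylate
partner
polymerize
potentiate
prenylate
protect
proteolyze
receptor
rescue
scaffold
secrete
sensitize
silence
substrate
sumoylate
synergy
titrate
transform
translocation
transport
transphosphorylate
uncouple
[iverb]
activate
associate
attach
bind
block
cleave
colocalize
combine
complex
connect
contact
cooperate
couple
dephosphorylate
dimerize
disrupt
enhance
form
heterodimerize
induce
inhibit
interact
interfere
link
mediate
methylate
modulate
phosphorylate
precipitate
promote
react
recognize
recruit
regulate
repress
require
sequester
stabilize
stimulate
suppress
target
tether
transactivate
trigger
ubiquitinate
[inoun]
adhesion
assembly
association
attachment
binding
cleavage
complex
contact
crosslink
degradation
dependence
dimer
dimerization
dissociation
formation
heterodimer
inhibition
interaction
ligation
linkage
modification
modulation
phosphorylation
reaction
recognition
recruitment
regulation
relation
repression
response
stabilization
stimulation
suppression
[second]
bind
interact
regulate
induce
stimulate
associate
known
[negative]
not
no
unable
incapable
cannot
fail
fails
failed
without
lack
lacks
lacking
neither
nor
never
absence
absent
[conjunctive]
where
when
what
why
how
as
though
although
because
so
therefore
hence
since
wherein
whereas
whereby
[condition]
if
whether
[prepositions]
about
above
across
after
against
along
among
around
at
before
behind
below
beneath
beside
between
beyond
by
despite
down
during
except
for
from
in
inside
into
near
of
off
on
onto
out
outside
over
through
throughout
to
toward
towards
under
underneath
until
up
upon
via
with
within
without
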