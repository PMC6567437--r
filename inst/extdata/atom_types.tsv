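code	element	description
C.ar	C	aromatic carbon
C.ntr	C	nitrile carbon (triple bond to N)
C.yne	C	alkyne carbon (triple bond to C)
C.cox	C	carboxyl/ester carbon (=O and single O)
C.amd	C	amide carbon (=O and single N)
C.car	C	carbonyl carbon, aldehyde or ketone (=O only)
C.ene	C	alkene carbon (double bond to C)
C.imn	C	imine carbon (double bond to N)
C.tho	C	thiocarbonyl carbon (double bond to S)
C.het	C	sp3 carbon with two or more single-bonded heteroatoms
C.alk	C	sp3 carbon, carbon/hydrogen neighbors only
C.olc	C	sp3 carbinol/ether carbon (one single-bonded O)
C.nlc	C	sp3 amine-bearing carbon (one single-bonded N)
C.slc	C	sp3 thiol/thioether-bearing carbon (one single-bonded S)
C.hal	C	sp3 halogen-bearing carbon
O.ar	O	aromatic oxygen
O.car	O	carbonyl oxygen (=C)
O.pd	O	phosphoryl oxygen (=P)
O.sd	O	sulfonyl oxygen (=S)
O.d	O	other double-bonded oxygen
O.pho	O	bridging phosphate-ester oxygen (two heavy neighbors, one P)
O.eth	O	ether/ester bridging oxygen (two heavy neighbors)
O.pt	O	terminal single-bonded oxygen on phosphorus
O.hyd	O	hydroxyl oxygen (one heavy neighbor)
N.ar	N	aromatic nitrogen
N.ntr	N	nitrile nitrogen
N.imn	N	imine nitrogen
N.am0	N	isolated nitrogen (ammonia-like)
N.am1	N	primary amine nitrogen
N.am2	N	secondary amine/amide nitrogen
N.am3	N	tertiary amine/amide nitrogen
S.ar	S	aromatic sulfur
S.oxo	S	oxidized sulfur (sulfoxide/sulfone/sulfonate)
S.thl	S	thiol sulfur (one heavy neighbor)
S.thi	S	thioether/disulfide sulfur
P.pho	P	phosphorus with oxygen neighbors (phosphate-like)
P.phn	P	phosphorus without oxygen neighbors (phosphine-like)
F	F	fluorine
Cl	Cl	chlorine
Br	Br	bromine
I	I	iodine
H	H	explicit hydrogen (normally collapsed to implicit counts)
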