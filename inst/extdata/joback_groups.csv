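group,smarts,tb,natoms,note
CH3,[CX4H3],23.58,1,methyl
CH2_chain,[CX4H2;!R],22.88,1,non-ring methylene
CH_chain,[CX4H1;!R],21.74,1,non-ring methine
C_chain,[CX4H0;!R],18.25,1,non-ring quaternary C
CH2_ring,[CX4H2;R],27.15,1,ring methylene
CH_ring,[CX4H1;R],21.78,1,ring methine
C_ring,[CX4H0;R],21.32,1,ring quaternary C
CH2_db,[CX3H2],18.18,1,terminal =CH2
CH_db_chain,[CX3H1;!R;!$([CX3]=[OX1])],24.96,1,non-ring =CH-
C_db_chain,[CX3H0;!R;!$([CX3]=[OX1])],24.14,1,non-ring =C<
C_allene,[CX2H0](=*)=*,26.15,1,cumulated =C=
C_alkyne_H,[CX2H1;$([CX2]#*)],9.20,1,terminal alkyne CH
C_alkyne,[CX2H0;$([CX2]#*);!$([CX2]#[NX1]);!$([CX2](=*)=*)],27.38,1,internal alkyne C
CH_db_ring,[CX3H1;R;!$([CX3]=[OX1])],26.73,1,ring =CH-
CH_db_ring,[cX3H1],26.73,1,aromatic CH
C_db_ring,[CX3H0;R;!$([CX3]=[OX1])],31.01,1,ring =C<
C_db_ring,[cX3H0],31.01,1,aromatic substituted C
F,[F],-0.03,1,fluorine
Cl,[Cl],38.13,1,chlorine
Br,[Br],66.86,1,bromine
I,[I],93.84,1,iodine
OH_alcohol,[OX2H1;$([OX2H1][CX4])],92.88,1,aliphatic hydroxyl
OH_phenol,[OX2H1;$([OX2H1][c])],76.34,1,phenolic hydroxyl
O_chain,[OX2H0;!R;!$([OX2][CX3]=[OX1])],22.42,1,non-ring ether O
O_ring,[OX2H0;R;!$([OX2][CX3]=[OX1])],31.22,1,ring ether O
O_ring,[oX2],31.22,1,aromatic ring O
CO_chain,[CX3H0;!R;$([CX3]=[OX1]);!$([CX3](=[OX1])[OX2])],76.75,2,non-ring carbonyl C=O
CO_ring,[CX3H0;R;$([CX3]=[OX1]);!$([CX3](=[OX1])[OX2])],94.97,2,ring carbonyl C=O
CHO,[CX3H1](=[OX1]),72.24,2,aldehyde
COOH,[CX3](=[OX1])[OX2H1],169.09,3,carboxylic acid
COO,[CX3](=[OX1])[OX2H0],81.10,3,ester / lactone
O_other,[OX1;!$([OX1]~[#6]);!$([OX1]~[NX3]~[OX1])],-10.50,1,=O outside C=O and nitro
NH2,[NX3H2],73.23,1,primary amine / amide NH2
NH_chain,[NX3H1;!R],50.17,1,non-ring secondary N-H
NH_ring,[NX3H1;R],52.82,1,ring secondary N-H
NH_ring,[nX3H1],52.82,1,aromatic N-H
N_chain,[NX3H0;!R;!$([NX3](~[OX1])~[OX1])],11.74,1,non-ring tertiary N
N_chain,[NX3H0;R;!$([NX3](~[OX1])~[OX1])],11.74,1,ring tertiary N (chain value)
Ndb_chain,[NX2H0;!R],74.60,1,non-ring -N=
Ndb_ring,[NX2H0;R],57.55,1,ring -N=
Ndb_ring,[nX2H0],57.55,1,aromatic N
NH_db,[NX2H1],83.08,1,=NH
CN,[CX2;$([CX2]#[NX1])],125.66,2,nitrile (C and N)
NO2,[NX3;$([NX3](~[OX1])~[OX1])],152.54,3,nitro (N and both O)
SH,[SX2H1],63.56,1,thiol
S_chain,[SX2H0;!R],68.78,1,non-ring sulfide S
S_ring,[SX2H0;R],52.10,1,ring sulfide S
S_ring,[sX2],52.10,1,aromatic S
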