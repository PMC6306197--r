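# Intron locations and per-taxon maximum insert lengths in 18S/28S rDNA
# of chaetocerotacean terminal taxa (transcribed from a published survey table).
# Cell grammar: 123 exact length; 123-134 length range; 123+ sequenced part of a
# longer insert (partial); ? presence unknown (omitted on parsing); empty = no
# insert. Suffix '^' marks a single-strain occurrence (intra-taxon polymorphism);
# suffix '!' marks a long insert with a spliceosomal 5' end, possibly an intron
# nested inside another.
gene	location	family	flank5	flank3	B_jadranum	B_furcatum_PMFBA4	B_furcatum_Na8A3	B_hyalinum_CCMP141	C_sp_Na13C2	C_sp_CDP22	C_circinalis	C_sp_Na17B2	C_sp_Na12A3	C_diversus_1	C_diversus_2	C_seiracanthus	C_rotosporus	C_decipiens_NaMC	C_sp_Na28A1	C_sp_Va7D2	C_anastomosans	C_vixvisibilis_1	C_vixvisibilis_2
SSU18S	1	SP	385	386										132	106+					?			
SSU18S	2	SP	442	443					90+	104		110	107	96	125					?			
SSU18S	3	SP	548	549					?	108										?			
SSU18S	4	GI	549	550	400	221+	399		?			360+	453		547	467	457	425	181+	?			
SSU18S	5	SP	888	889					130			124	110^										
SSU18S	6	SP	889	890										121									
SSU18S	7	SP	891	892		115		57+															
SSU18S	8	SP	981	982						?			51+	123						?			
SSU18S	9	SP	989	990					162	?	100	107			160-199					?	123		
SSU18S	10	SP	1011	1012		92+			115	?			96	109	161				124	?			
SSU18S	11	SP	1147	1148		?			112	?		101	94	104	133^				141	?			
SSU18S	12	GI	1151	1152		?				?						462-465	505-513			?			
SSU18S	13	SP	1195	1196		?			152	71+	110	100	104	105	121				141	?			
SSU18S	14	SP	1257	1258		?					?	392+!								?			
SSU18S	15	SP	1274	1275		?			80	106	?	102			86-96				134	?			342+!
SSU18S	16	SP	1414	1415		?			117		106+	99	108	35+	153					?			
SSU18S	17	SP	1612	1613	?	?							98							?			
SSU18S	18	SP	1615	1616	?	?			115	116		118		117	96-97			15^		?		154	98-154
SSU18S	19	SP	1760	1761	?	?	?	?	109+	?	?	?	?	91+	91+	?	?	94+	92+	?	73+	?	?
LSU28S	1	SP	758	759					112			108	112-116		115				205+	94-105			
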