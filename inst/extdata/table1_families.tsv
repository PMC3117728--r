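individual	A.1	A.2	A.3	A.4	B.1	B.2	B.3	B.4	C.1	C.2	C.3	C.4	D.1	D.2	D.3	D.4	E.1	E.2	E.3	E.4
Father	3	4			2	6			5	13			4	9			2	6		
Mother			4	15			1	8			2	8			6	16			1	11
Juvenile 1		4	4			6	1			13	2		4		6			6		11
Juvenile 2	3			15		6		8	5		2		4			16	2			11
Juvenile 3		4		15		6	1		5		2			9		16		6	1	
Juvenile 4		4		15		6	1			13		8	4		6		2			11
Juvenile 5	3			15		6		8	5			8		9		16		6	1	
Juvenile 6	3			15	2		1			13		8		9	6		2		1	
Juvenile 7	3		4			6		8		13		8		9	6		2		1	
Juvenile 8		4	4			6		8		13		8	4			16	2			11
Juvenile 9	3			15	2		1		5			8								
Juvenile 10	3			15																
Juvenile 11	3		4																	
Juvenile 12	3			15																
Juvenile 13		4		15																
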