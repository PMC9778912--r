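label	class	standard_label
PC aa C30:0	PC_AA	06:0 PC (DHPC)
PC aa C30:1	PC_AA	06:0 PC (DHPC)
PC aa C30:2	PC_AA	06:0 PC (DHPC)
PC aa C32:0	PC_AA	06:0 PC (DHPC)
PC aa C32:1	PC_AA	06:0 PC (DHPC)
PC aa C32:2	PC_AA	06:0 PC (DHPC)
PC aa C32:3	PC_AA	06:0 PC (DHPC)
PC aa C34:1	PC_AA	06:0 PC (DHPC)
PC aa C34:2	PC_AA	06:0 PC (DHPC)
PC aa C34:3	PC_AA	06:0 PC (DHPC)
PC aa C34:4	PC_AA	06:0 PC (DHPC)
PC aa C36:0	PC_AA	06:0 PC (DHPC)
PC aa C36:1	PC_AA	06:0 PC (DHPC)
PC aa C36:2	PC_AA	06:0 PC (DHPC)
PC aa C36:3	PC_AA	06:0 PC (DHPC)
PC aa C36:4	PC_AA	06:0 PC (DHPC)
PC aa C36:5	PC_AA	06:0 PC (DHPC)
PC aa C36:6	PC_AA	06:0 PC (DHPC)
PC aa C38:0	PC_AA	06:0 PC (DHPC)
PC aa C38:1	PC_AA	06:0 PC (DHPC)
PC aa C38:2	PC_AA	06:0 PC (DHPC)
PC aa C38:3	PC_AA	06:0 PC (DHPC)
PC aa C38:4	PC_AA	06:0 PC (DHPC)
PC aa C38:5	PC_AA	06:0 PC (DHPC)
PC aa C38:6	PC_AA	06:0 PC (DHPC)
PC aa C40:0	PC_AA	06:0 PC (DHPC)
PC aa C40:1	PC_AA	06:0 PC (DHPC)
PC aa C40:2	PC_AA	06:0 PC (DHPC)
PC aa C40:3	PC_AA	06:0 PC (DHPC)
PC aa C40:4	PC_AA	06:0 PC (DHPC)
PC aa C40:5	PC_AA	06:0 PC (DHPC)
PC aa C40:6	PC_AA	06:0 PC (DHPC)
PC aa C42:0	PC_AA	06:0 PC (DHPC)
PC aa C42:1	PC_AA	06:0 PC (DHPC)
PC aa C42:2	PC_AA	06:0 PC (DHPC)
PC aa C42:3	PC_AA	06:0 PC (DHPC)
PC aa C42:4	PC_AA	06:0 PC (DHPC)
PC aa C42:5	PC_AA	06:0 PC (DHPC)
PC aa C42:6	PC_AA	06:0 PC (DHPC)
PC aa C44:0	PC_AA	06:0 PC (DHPC)
PC aa C26:0	PC_AA	06:0 PC (DHPC)
PC aa C28:0	PC_AA	06:0 PC (DHPC)
PC aa C28:1	PC_AA	06:0 PC (DHPC)
PC ae C30:0	PC_AE	PC ae standard (Splash Lipidomix)
PC ae C30:1	PC_AE	PC ae standard (Splash Lipidomix)
PC ae C30:2	PC_AE	PC ae standard (Splash Lipidomix)
PC ae C32:1	PC_AE	PC ae standard (Splash Lipidomix)
PC ae C32:2	PC_AE	PC ae standard (Splash Lipidomix)
PC ae C34:0	PC_AE	PC ae standard (Splash Lipidomix)
PC ae C34:1	PC_AE	PC ae standard (Splash Lipidomix)
PC ae C34:2	PC_AE	PC ae standard (Splash Lipidomix)
PC ae C34:3	PC_AE	PC ae standard (Splash Lipidomix)
PC ae C36:0	PC_AE	PC ae standard (Splash Lipidomix)
PC ae C36:1	PC_AE	PC ae standard (Splash Lipidomix)
PC ae C36:2	PC_AE	PC ae standard (Splash Lipidomix)
PC ae C36:3	PC_AE	PC ae standard (Splash Lipidomix)
PC ae C36:4	PC_AE	PC ae standard (Splash Lipidomix)
PC ae C36:5	PC_AE	PC ae standard (Splash Lipidomix)
PC ae C38:0	PC_AE	PC ae standard (Splash Lipidomix)
PC ae C38:1	PC_AE	PC ae standard (Splash Lipidomix)
PC ae C38:2	PC_AE	PC ae standard (Splash Lipidomix)
PC ae C38:3	PC_AE	PC ae standard (Splash Lipidomix)
PC ae C38:4	PC_AE	PC ae standard (Splash Lipidomix)
PC ae C38:5	PC_AE	PC ae standard (Splash Lipidomix)
PC ae C38:6	PC_AE	PC ae standard (Splash Lipidomix)
PC ae C40:0	PC_AE	PC ae standard (Splash Lipidomix)
PC ae C40:1	PC_AE	PC ae standard (Splash Lipidomix)
PC ae C40:2	PC_AE	PC ae standard (Splash Lipidomix)
PC ae C40:3	PC_AE	PC ae standard (Splash Lipidomix)
PC ae C40:4	PC_AE	PC ae standard (Splash Lipidomix)
PC ae C40:5	PC_AE	PC ae standard (Splash Lipidomix)
PC ae C40:6	PC_AE	PC ae standard (Splash Lipidomix)
PC ae C42:0	PC_AE	PC ae standard (Splash Lipidomix)
PC ae C42:1	PC_AE	PC ae standard (Splash Lipidomix)
PC ae C42:2	PC_AE	PC ae standard (Splash Lipidomix)
PC ae C42:3	PC_AE	PC ae standard (Splash Lipidomix)
PC ae C42:4	PC_AE	PC ae standard (Splash Lipidomix)
PC ae C42:5	PC_AE	PC ae standard (Splash Lipidomix)
PC ae C44:3	PC_AE	PC ae standard (Splash Lipidomix)
PC ae C44:4	PC_AE	PC ae standard (Splash Lipidomix)
PC ae C44:5	PC_AE	PC ae standard (Splash Lipidomix)
PC ae C44:6	PC_AE	PC ae standard (Splash Lipidomix)
lyso-PC C6:0	LYSO_PC	19:0 Lyso PC
lyso-PC C8:0	LYSO_PC	19:0 Lyso PC
lyso-PC C12:0	LYSO_PC	19:0 Lyso PC
lyso-PC C14:0	LYSO_PC	19:0 Lyso PC
lyso-PC C15:0	LYSO_PC	19:0 Lyso PC
lyso-PC C16:0	LYSO_PC	19:0 Lyso PC
lyso-PC C16:1	LYSO_PC	19:0 Lyso PC
lyso-PC C17:0	LYSO_PC	19:0 Lyso PC
lyso-PC C18:0	LYSO_PC	19:0 Lyso PC
lyso-PC C18:1	LYSO_PC	19:0 Lyso PC
lyso-PC C18:2	LYSO_PC	19:0 Lyso PC
lyso-PC C18:3	LYSO_PC	19:0 Lyso PC
lyso-PC C20:0	LYSO_PC	19:0 Lyso PC
lyso-PC C20:3	LYSO_PC	19:0 Lyso PC
lyso-PC C20:4	LYSO_PC	19:0 Lyso PC
lyso-PC C22:5	LYSO_PC	19:0 Lyso PC
lyso-PC C22:6	LYSO_PC	19:0 Lyso PC
lyso-PC C24:0	LYSO_PC	19:0 Lyso PC
lyso-PC C26:0	LYSO_PC	19:0 Lyso PC
lyso-PC C26:1	LYSO_PC	19:0 Lyso PC
lyso-PC C28:0	LYSO_PC	19:0 Lyso PC
lyso-PC C28:1	LYSO_PC	19:0 Lyso PC
SM C14:0	SM	06:0 SM (d18:1/6:0)
SM C16:0	SM	06:0 SM (d18:1/6:0)
SM C16:1	SM	06:0 SM (d18:1/6:0)
SM C18:0	SM	06:0 SM (d18:1/6:0)
SM C18:1	SM	06:0 SM (d18:1/6:0)
SM C18:2	SM	06:0 SM (d18:1/6:0)
SM C20:0	SM	06:0 SM (d18:1/6:0)
SM C20:1	SM	06:0 SM (d18:1/6:0)
SM C20:2	SM	06:0 SM (d18:1/6:0)
SM C22:0	SM	06:0 SM (d18:1/6:0)
SM C22:1	SM	06:0 SM (d18:1/6:0)
SM C24:0	SM	06:0 SM (d18:1/6:0)
SM C24:1	SM	06:0 SM (d18:1/6:0)
SM C26:0	SM	06:0 SM (d18:1/6:0)
SM C26:1	SM	06:0 SM (d18:1/6:0)
TAG 44:0	TAG	TAG standard (Splash Lipidomix)
TAG 46:0	TAG	TAG standard (Splash Lipidomix)
TAG 46:1	TAG	TAG standard (Splash Lipidomix)
TAG 48:0	TAG	TAG standard (Splash Lipidomix)
TAG 48:1	TAG	TAG standard (Splash Lipidomix)
TAG 48:2	TAG	TAG standard (Splash Lipidomix)
TAG 50:0	TAG	TAG standard (Splash Lipidomix)
TAG 50:1	TAG	TAG standard (Splash Lipidomix)
TAG 50:2	TAG	TAG standard (Splash Lipidomix)
TAG 50:3	TAG	TAG standard (Splash Lipidomix)
TAG 52:1	TAG	TAG standard (Splash Lipidomix)
TAG 52:2	TAG	TAG standard (Splash Lipidomix)
TAG 52:3	TAG	TAG standard (Splash Lipidomix)
TAG 54:2	TAG	TAG standard (Splash Lipidomix)
TAG 54:3	TAG	TAG standard (Splash Lipidomix)
TAG 54:4	TAG	TAG standard (Splash Lipidomix)
TAG 56:3	TAG	TAG standard (Splash Lipidomix)
C0	CARNITINE	octanoyl-L-carnitine d3
C2	CARNITINE	octanoyl-L-carnitine d3
C3	CARNITINE	octanoyl-L-carnitine d3
C3 OH	CARNITINE	octanoyl-L-carnitine d3
C3:1	CARNITINE	octanoyl-L-carnitine d3
C4	CARNITINE	octanoyl-L-carnitine d3
C4 OH	CARNITINE	octanoyl-L-carnitine d3
C4:1	CARNITINE	octanoyl-L-carnitine d3
C5	CARNITINE	octanoyl-L-carnitine d3
C5 OH	CARNITINE	octanoyl-L-carnitine d3
C5:1	CARNITINE	octanoyl-L-carnitine d3
C6	CARNITINE	octanoyl-L-carnitine d3
C6 OH	CARNITINE	octanoyl-L-carnitine d3
C6:1	CARNITINE	octanoyl-L-carnitine d3
C7	CARNITINE	octanoyl-L-carnitine d3
C8	CARNITINE	octanoyl-L-carnitine d3
C8:1	CARNITINE	octanoyl-L-carnitine d3
C9	CARNITINE	octanoyl-L-carnitine d3
C10	CARNITINE	octanoyl-L-carnitine d3
C10:1	CARNITINE	octanoyl-L-carnitine d3
C10:2	CARNITINE	octanoyl-L-carnitine d3
C11	CARNITINE	octanoyl-L-carnitine d3
C12	CARNITINE	octanoyl-L-carnitine d3
C12:1	CARNITINE	octanoyl-L-carnitine d3
C12 OH	CARNITINE	octanoyl-L-carnitine d3
C12:1 OH	CARNITINE	octanoyl-L-carnitine d3
C13	CARNITINE	octanoyl-L-carnitine d3
C14	CARNITINE	octanoyl-L-carnitine d3
C14:1	CARNITINE	octanoyl-L-carnitine d3
C14:2	CARNITINE	octanoyl-L-carnitine d3
C14 OH	CARNITINE	octanoyl-L-carnitine d3
C16	CARNITINE	octanoyl-L-carnitine d3
C16:1	CARNITINE	octanoyl-L-carnitine d3
C16:2	CARNITINE	octanoyl-L-carnitine d3
C16 OH	CARNITINE	octanoyl-L-carnitine d3
C16:1 OH	CARNITINE	octanoyl-L-carnitine d3
C18	CARNITINE	octanoyl-L-carnitine d3
C18:1	CARNITINE	octanoyl-L-carnitine d3
C18:2	CARNITINE	octanoyl-L-carnitine d3
C18 OH	CARNITINE	octanoyl-L-carnitine d3
C18:1 OH	CARNITINE	octanoyl-L-carnitine d3
Cholesterol total	CHOLESTEROL_TOTAL	cholesterol-d7 (total)
Cholesterol free	CHOLESTEROL_FREE	cholesterol-d7 (free)
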