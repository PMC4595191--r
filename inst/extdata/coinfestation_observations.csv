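site_id,animal_id,inspection_mode,species,sex,body_region,cluster_id,partner_species
SY1,C01,laid_down,Av,M,inguinal,c1,
SY1,C01,laid_down,Ah,M,inguinal,c1,
SY2,C02,laid_down,Av,M,inguinal,c1,
SY2,C02,laid_down,Ah,M,inguinal,c1,
SY3,C03,laid_down,Av,M,inguinal,c1,
SY3,C03,laid_down,Ah,M,inguinal,c1,
SY4,C04,laid_down,Av,M,inguinal,c1,
SY4,C04,laid_down,Ah,M,inguinal,c1,
SY5,C05,laid_down,Av,M,inguinal,c1,
SY5,C05,laid_down,Ah,M,inguinal,c1,
SY1,C06,laid_down,Av,M,inguinal,c1,
SY1,C06,laid_down,Ah,M,inguinal,c1,
SY2,C07,laid_down,Av,M,inguinal,c1,
SY2,C07,laid_down,Ah,M,inguinal,c1,
SY3,C08,laid_down,Av,M,inguinal,c1,
SY3,C08,laid_down,Ah,M,inguinal,c1,
SY4,C09,laid_down,Av,M,inguinal,c1,
SY4,C09,laid_down,Ah,M,inguinal,c1,
SY5,C10,laid_down,Av,M,inguinal,c1,
SY5,C10,laid_down,Ah,M,inguinal,c1,
SY1,C11,laid_down,Av,M,inguinal,c1,
SY1,C11,laid_down,Ah,M,inguinal,c1,
SY2,C12,laid_down,Av,M,inguinal,c1,
SY2,C12,laid_down,Ah,M,inguinal,c1,
SY3,C13,laid_down,Av,M,inguinal,c1,
SY3,C13,laid_down,Ah,M,inguinal,c1,
SY4,C14,laid_down,Av,M,inguinal,c1,
SY4,C14,laid_down,Ah,M,inguinal,c1,
SY5,C15,laid_down,Av,M,inguinal,c1,
SY5,C15,laid_down,Ah,M,inguinal,c1,
SY1,C16,laid_down,Av,M,inguinal,c1,
SY1,C16,laid_down,Ah,M,inguinal,c1,
SY2,C17,laid_down,Av,M,inguinal,c1,
SY2,C17,laid_down,Ah,M,inguinal,c1,
SY3,C18,laid_down,Av,M,inguinal,c1,
SY3,C18,laid_down,Ah,M,inguinal,c1,
SY4,C19,laid_down,Av,M,inguinal,c1,
SY4,C19,laid_down,Ah,M,inguinal,c1,
SY5,C20,laid_down,Av,M,inguinal,c1,
SY5,C20,laid_down,Ah,M,inguinal,c1,
SY1,C21,laid_down,Av,M,inguinal,c1,
SY1,C21,laid_down,Ah,M,inguinal,c1,
SY2,C22,laid_down,Av,M,inguinal,c1,
SY2,C22,laid_down,Ah,M,inguinal,c1,
SY3,C23,laid_down,Av,M,inguinal,c1,
SY3,C23,laid_down,Ah,M,inguinal,c1,
SY4,C24,laid_down,Av,M,inguinal,c1,
SY4,C24,laid_down,Ah,M,inguinal,c1,
SY5,C25,laid_down,Av,M,inguinal,c1,
SY5,C25,laid_down,Ah,M,inguinal,c1,
SY1,C26,laid_down,Av,M,inguinal,c1,
SY1,C26,laid_down,Ah,M,inguinal,c1,
SY2,C27,laid_down,Av,M,inguinal,c1,
SY2,C27,laid_down,Ah,M,inguinal,c1,
SY3,C28,laid_down,Av,M,inguinal,c1,
SY3,C28,laid_down,Ah,M,inguinal,c1,
SY4,C29,laid_down,Av,M,inguinal,c1,
SY4,C29,laid_down,Ah,M,inguinal,c1,
SY5,C30,laid_down,Av,M,inguinal,c1,
SY5,C30,laid_down,Ah,M,inguinal,c1,
SY1,C31,laid_down,Av,M,inguinal,c1,
SY1,C31,laid_down,Ah,M,inguinal,c1,
SY2,C32,laid_down,Av,M,inguinal,c1,
SY2,C32,laid_down,Ah,M,inguinal,c1,
SY3,C33,laid_down,Av,M,inguinal,c1,
SY3,C33,laid_down,Ah,M,inguinal,c1,
SY4,C34,laid_down,Av,M,inguinal,c1,
SY4,C34,laid_down,Ah,M,inguinal,c1,
SY5,C35,laid_down,Av,M,inguinal,c1,
SY5,C35,laid_down,Ah,M,inguinal,c1,
SY1,C36,laid_down,Av,M,inguinal,c1,
SY1,C36,laid_down,Ah,M,inguinal,c1,
SY2,C37,laid_down,Av,M,inguinal,c1,
SY3,C38,laid_down,Av,M,inguinal,c1,
SY4,C39,laid_down,Av,M,inguinal,c1,
SY5,C40,laid_down,Av,M,inguinal,c1,
SY1,C41,laid_down,Av,M,inguinal,c1,
SY2,C42,laid_down,Av,M,inguinal,c1,
SY3,C43,laid_down,Av,M,inguinal,c1,
SY4,C44,laid_down,Av,M,inguinal,c1,
SY5,C45,laid_down,Av,M,inguinal,c1,
SY1,C46,laid_down,Av,M,inguinal,c1,
SY2,C47,laid_down,Av,M,inguinal,c1,
SY3,C48,laid_down,Av,M,inguinal,c1,
SY4,C49,laid_down,Av,M,inguinal,c1,
SY5,C50,laid_down,Av,M,inguinal,c1,
SY1,C51,laid_down,Av,M,inguinal,c1,
SY2,C52,laid_down,Av,M,inguinal,c1,
SY3,C53,laid_down,Av,M,inguinal,c1,
SY4,C54,laid_down,Av,M,inguinal,c1,
SY5,C55,laid_down,Av,M,inguinal,c1,
SY1,C56,laid_down,Av,M,inguinal,c1,
SY2,C57,laid_down,Av,M,inguinal,c1,
SY3,C58,laid_down,Ah,M,inguinal,c1,
SY4,C59,laid_down,Ah,M,inguinal,c1,
SY5,C60,laid_down,Ah,M,inguinal,c1,
SY1,C61,laid_down,Ah,M,inguinal,c1,
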