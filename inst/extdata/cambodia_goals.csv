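id,name,definition
1,no poverty,End poverty in all its forms everywhere
2,zero hunger,"End hunger, achieve food security and improved nutrition and promote sustainable agriculture"
3,child health,"Child health: a state of complete physical, mental and social well-being and not merely the absence of disease or infirmity among human beings below 18 years"
4,quality education,Ensure inclusive and equitable quality education and promote lifelong learning opportunities for all
5,gender equality,Achieve gender equality and empower all women and girls
6,clean water and sanitation,Ensure availability and sustainable management of water and sanitation for all
7,affordable and clean energy,"Ensure access to affordable, reliable, sustainable and modern energy for all"
8,decent work and economic growth,"Promote sustained, inclusive and sustainable economic growth, full and productive employment and decent work for all"
9,"industry, innovation and infrastructure","Build resilient infrastructure, promote inclusive and sustainable industrialization and foster innovation"
10,reduced inequalities,Reduce inequality within and among countries
11,sustainable cities and communities,"Make cities and human settlements inclusive, safe, resilient and sustainable"
12,responsible consumption and production,Ensure sustainable consumption and production patterns
13,climate change,Take urgent action to combat climate change and its impacts
14,life below water,"Conserve and sustainably use the oceans, seas and marine resources for sustainable development"
15,life on land,"Protect, restore and promote sustainable use of terrestrial ecosystems, sustainably manage forests, combat desertification, and halt and reverse land degradation and halt biodiversity loss"
16,"peace, justice and strong institutions","Promote peaceful and inclusive societies for sustainable development, provide access to justice for all and build effective, accountable and inclusive institutions at all levels"
18,mine/ERW free,End the negative impact of Mine/Explosive remnants of war (ERW) and promote victim assistance
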