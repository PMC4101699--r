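gene_id	S001	S002	S003	S004	S005	S006	S007	S008	S009	S010	S011	S012
G00001	9.625968539113803	10.378362935923949	10.637434168401686	11.257403046318498	9.628178789294187	10.015739195568788	11.905661681834255	10.055508432988493	11.882419436293008	10.960281429161146	13.366415896471553	12.051816902893545
G00002	6.895683360136938	6.369113802025492	7.921131480740458	8.197703830073593	6.539281136456372	5.601407920558278	7.7039456127667	9.486729940339437	9.668620471553897	9.202003193843463	9.62334614277981	9.913194910567922
G00003	6.781529531811229	10.120420136797986	9.008460205546175	7.54148397016616	6.520014771586901	9.71186216624169	11.18770131704799	11.716017744364803	10.310327339700088	9.34619676044823	9.302022346431407	10.583683529878572
G00004	9.409391262272832	9.592193213158877	8.063517610031882	10.797775809114308	7.724545957081575	8.67564820606748	11.432487771256328	13.008833149740866	10.29079048161979	11.139312906001308	12.330869363827095	11.684366049056003
G00005	7.966407608751379	8.696163131311105	7.506621586063643	7.939629075953682	8.785918925829437	8.138557160039245	10.60004685829011	9.229540886470978	11.856639088790216	11.904108384316164	11.810861421721322	10.459929857712629
G00006	8.296263349103993	8.117363973154237	9.353520235667702	7.946327038318843	8.408433820286309	6.602560897876559	7.992269118725198	6.6899576602356685	7.569049510751377	6.806939502898023	8.664887189544654	7.782925890481491
G00007	10.972120333387227	10.94657181221368	10.52520443369044	9.845027114289554	9.774405642604934	10.259520962381082	9.683174025808604	9.561461601398287	11.215234992033604	9.528842241945345	8.604653593972815	10.749652462262942
G00008	8.893114964350277	7.947844328959436	7.946451671539941	7.735661270425383	7.858074326445705	7.057729264428694	8.226818175010596	6.803955660303163	6.656429012271416	7.904575381831218	7.288705098774873	8.850955079156089
G00009	10.41870919540835	8.034545487662626	10.906739033276473	11.21582860531706	12.150525214195529	10.494143240865126	11.322289910535078	10.38189184767307	10.56151947444006	10.010039450989456	11.663149388105088	9.78124007278352
G00010	8.410883974719338	8.190811804952027	6.71159995626084	8.025089809418375	9.345784594397559	9.193604097005958	7.626669478078793	7.720550883744865	7.6365774562681885	7.52264489153509	7.9496508589992265	7.872441326575759
G00011	8.240295802261885	9.590069838594253	10.569301379375615	9.932211930467826	8.860190712929407	9.7817786110931	8.621067826442074	8.756082430595242	9.566339073204368	10.830059893006627	10.305316784996535	9.886342300085232
G00012	10.645509080672163	11.615198653917268	11.212828243305138	11.538040816993691	11.312648528801482	10.358185704900983	12.130716907491694	13.46694025603481	12.778675101043373	12.399513103021777	13.889561637922075	10.671047435320709
G00013	5.065801354154973	6.498532675696998	5.73395224199957	5.431273712484824	7.118207349251192	6.079915830798874	6.470905570605525	6.0244836932170385	5.893944247033079	6.300555613358586	5.098328623931822	4.882349587392339
G00014	5.167609199827311	8.981553677066621	8.515163178345103	7.077599719086039	7.112087269207642	7.219078434145993	6.745510256972528	7.497708749268362	7.826042700877393	5.730261186706478	5.468616734844806	6.951084895803123
G00015	7.836140602301768	7.072725935935048	8.621791105917762	6.138918915494701	7.747548510470517	8.390031543396852	6.20542983340327	8.295637637014107	6.85764628754559	7.746021258583347	8.073713267839928	8.386825715422507
G00016	9.159924197305365	10.256468229149256	10.346041973039384	8.571591870231295	8.867818298868022	10.386347524836102	9.158884177692746	8.991340783223077	8.224708320595537	10.018698811443397	8.2663287558617	8.53760294092146
G00017	7.212563319327225	7.909468737627966	7.097446694821217	7.060970359998091	6.6859415999694605	6.580928106766399	7.228532639903002	7.441532580919982	8.57168952643074	8.386815655287498	8.019661670837758	6.788732808370571
G00018	4.773480104342353	5.053822967340457	4.665665429369142	6.717207868987634	3.570632863758098	4.469967166223118	4.267928572007291	5.492104292194933	5.273798533238397	3.8245003945385547	3.2029321448522388	4.178733188128933
G00019	3.612594780060146	5.260028175427367	5.730410063526722	2.9771833759470026	4.3098547280484825	4.424197665815208	3.0452971416521675	4.122269397044618	5.588163295946817	1.6393697985730182	6.5513550874718565	3.102585372027371
G00020	8.611888974175994	10.70104818146215	8.86938113914739	10.117426237153895	9.566301169537365	10.875735600859834	9.020999574214926	8.696567814503062	8.599532969069958	10.041136657396406	9.856464047017859	11.02604379483196
G00021	7.972860134771005	6.496923170314433	6.679249522004445	6.046417041565997	8.653428132250491	7.310263969936021	8.625816962562189	7.92570999932569	9.590002802518683	8.113793806365866	7.062706602852236	7.055446692663579
G00022	4.516644172843328	5.237850962419293	4.1962986681762295	3.857601607593203	4.847044507376018	6.1646564174906135	5.731812253745714	4.9765244755009075	6.344910178829542	5.373840928755099	5.161775857543391	5.517166160710665
G00023	9.18622522808182	8.365642128360111	6.282909966858172	7.866826352557575	7.308954933759839	5.9970681050238746	8.328611503079866	7.220327873004298	7.71540650222231	7.899536506536443	8.604687349987	7.793130297935541
G00024	9.390565846145552	8.868488690986554	9.901994602000059	8.825372913874862	10.518874625311001	11.511470970072272	11.63724049491285	8.753880848071727	10.52561982755716	10.25357742162767	9.919352533961717	9.821771379872457
G00025	11.498438075299655	10.29996137732359	11.495994531546637	10.84096757759274	9.78642177872654	11.707568170416026	10.97161162049983	11.271156095164141	9.871404962745585	10.446240455847235	9.21717345268616	12.652172234340314
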